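test_that("class counts, vocabularies and split match the configuration", {
  cfg <- cohort_config(n_pos = 328, n_neg = 110, n_unknown = 14,
                       n_mirnas = 60, n_genes = 0, n_de = 6,
                       dc_module_size = 5, signature_size = 4,
                       n_targets_per_sig = 0, label_noise = 0,
                       test_fraction_or_counts = 0.2, seed = 3)
  co <- generate_cohort(cfg)
  ann <- co$annotation
  # with label_noise = 0 the observed labels are the exact class counts
  expect_equal(sum(ann$label == "positive"), 328)
  expect_equal(sum(ann$label == "negative"), 110)
  expect_equal(sum(ann$label == "unknown"), 14)
  expect_equal(dim(co$mirna), c(60, 452))
  expect_true(all(co$mirna >= 0 & co$mirna == floor(co$mirna)))
  expect_false(anyDuplicated(rownames(co$mirna)) > 0)
  expect_false(anyDuplicated(ann$sample_id) > 0)
  expect_setequal(unique(ann$split), c("train", "test"))
  expect_true(all(ann$ajcc_t %in% c(paste0("T", 1:4), "TX")))
  # planted sets respect the configured overlap structure
  expect_length(co$truth$signature_ids, 4)
  expect_true(all(co$truth$signature_ids %in% co$truth$de_ids$feature_id))
  expect_true(all(co$truth$signature_ids %in% co$truth$dc_ids))
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_pos = 30, n_neg = 20, n_unknown = 2,
                       n_mirnas = 40, n_genes = 30, n_de = 4,
                       dc_module_size = 3, signature_size = 2,
                       n_targets_per_sig = 2, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
})

test_that("planted DE features show the requested fold change on average", {
  # Monte-Carlo oracle: empirical log2 ratio of group means, averaged over
  # replicates, against the planted signed effect of exactly 1
  reps <- 30
  err <- vapply(200 + seq_len(reps), function(seed) {
    cfg <- cohort_config(n_pos = 200, n_neg = 200, n_unknown = 0,
                         n_mirnas = 100, n_genes = 0, n_de = 10,
                         de_log2fc_range = c(1, 1), dc_module_size = 0,
                         signature_size = 0, n_targets_per_sig = 0,
                         label_noise = 0, nb_dispersion = 0.1,
                         test_fraction_or_counts = 0, seed = seed)
    co <- generate_cohort(cfg)
    rpm <- compute_rpm(co$mirna)
    pos <- co$annotation$label == "positive"
    ids <- co$truth$de_ids$feature_id
    emp <- log2(rowMeans(rpm[ids, pos]) / rowMeans(rpm[ids, !pos]))
    mean(emp * sign(co$truth$de_ids$log2fc))
  }, numeric(1))
  expect_lt(abs(mean(err) - 1), 0.15)
})

test_that("co-expression module is correlated only in the positive condition", {
  cfg <- cohort_config(n_pos = 150, n_neg = 150, n_unknown = 0,
                       n_mirnas = 100, n_genes = 0, n_de = 0,
                       dc_module_size = 8, dc_rho = 0.7, signature_size = 0,
                       n_targets_per_sig = 0, label_noise = 0,
                       test_fraction_or_counts = 0, seed = 17)
  co <- generate_cohort(cfg)
  lx <- log2(compute_rpm(co$mirna) + 1)
  pos <- co$annotation$label == "positive"
  mod <- co$truth$dc_ids
  mean_offdiag <- function(C) mean(C[upper.tri(C)])
  c_pos <- mean_offdiag(cor(t(lx[mod, pos]), method = "spearman"))
  c_neg <- mean_offdiag(cor(t(lx[mod, !pos]), method = "spearman"))
  expect_lt(abs(c_pos - 0.7), 0.15)
  expect_lt(abs(c_neg), 0.1)
})

test_that("planted target genes are negatively coupled to their miRNA", {
  cfg <- cohort_config(n_pos = 150, n_neg = 50, n_unknown = 0,
                       n_mirnas = 60, n_genes = 300, n_de = 6,
                       dc_module_size = 5, signature_size = 4,
                       n_targets_per_sig = 5, target_rho = -0.6,
                       test_fraction_or_counts = 0, seed = 23)
  co <- generate_cohort(cfg)
  mir <- log2(compute_rpm(co$mirna) + 1)
  gen <- log2(compute_rpm(co$mrna) + 1)
  links <- co$truth$target_links
  rho <- vapply(seq_len(nrow(links)), function(i)
    cor(mir[links$mirna_id[i], ], gen[links$gene_id[i], ],
        method = "spearman"), numeric(1))
  expect_lt(mean(rho), -0.35)
  expect_gt(mean(rho < -0.25), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_de = 3, dc_module_size = 5,
                             signature_size = 4),
               "signature_size")
  expect_error(cohort_config(label_noise = 0.6), "label_noise")
  expect_error(cohort_config(target_rho = 0.3), "target_rho")
  expect_error(cohort_config(n_pos = 4, n_neg = 3), "at least 10")
  expect_error(cohort_config(de_log2fc_range = c(2, 1)), "de_log2fc_range")
})

test_that("write_cohort / read_cohort round-trips exactly", {
  cfg <- cohort_config(n_pos = 20, n_neg = 15, n_unknown = 3,
                       n_mirnas = 25, n_genes = 20, n_de = 3,
                       dc_module_size = 3, signature_size = 2,
                       n_targets_per_sig = 2, seed = 7)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(dir, co)
  back <- read_cohort(dir)
  expect_equal(back$mirna, co$mirna)
  expect_equal(back$mrna, co$mrna)
  expect_equal(back$annotation, co$annotation)
  expect_equal(back$truth$signature_ids, co$truth$signature_ids)
  expect_equal(back$truth$de_ids$log2fc, co$truth$de_ids$log2fc)
  expect_equal(back$truth$condition, co$truth$condition)
})

test_that("malformed cohort files raise parse errors naming the culprit", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(
    n_pos = 8, n_neg = 4, n_unknown = 0, n_mirnas = 5, n_genes = 0,
    n_de = 0, dc_module_size = 0, signature_size = 0,
    n_targets_per_sig = 0, test_fraction_or_counts = 0, seed = 1))
  write_cohort(dir, co)

  # duplicated sample column
  lines <- readLines(file.path(dir, "mirna.tsv"))
  hdr <- strsplit(lines[1], "\t")[[1]]
  hdr[3] <- hdr[2]
  writeLines(c(paste(hdr, collapse = "\t"), lines[-1]),
             file.path(dir, "mirna.tsv"))
  expect_error(read_cohort(dir), "duplicated sample column")

  write_cohort(dir, co)
  ann <- co$annotation
  ann$label[1] <- "yes"
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(dir), "allowed values")

  write_cohort(dir, co)
  lines <- readLines(file.path(dir, "mirna.tsv"))
  flds <- strsplit(lines[2], "\t")[[1]]
  flds[2] <- "3.5"
  lines[2] <- paste(flds, collapse = "\t")
  writeLines(lines, file.path(dir, "mirna.tsv"))
  expect_error(read_cohort(dir), "non-integer")
})
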