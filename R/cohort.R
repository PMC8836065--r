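#' Configure a synthetic melanoma-style miRNA-Seq cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate a melanoma recurrence cohort of the kind that motivates
#' the package: 328 positive (recurrent) and 110 negative samples plus 14
#' with unknown recurrence status, overdispersed negative-binomial miRNA counts
#' with variable library sizes, a planted set of differentially expressed
#' (DE) miRNAs, a co-expression module active only in the positive
#' condition, and a planted signature equal to the overlap of the two.
#'
#' @param n_pos,n_neg Number of positive- and negative-condition samples.
#' @param n_unknown Samples whose label is recorded as `"unknown"`.
#' @param n_mirnas,n_genes Total miRNA and mRNA features (`n_genes = 0`
#'   suppresses the mRNA matrix).
#' @param n_de Number of planted DE miRNAs.
#' @param de_log2fc_range Length-2 numeric, low/high absolute log2
#'   fold change of planted DE effects (signs are drawn at random).
#' @param dc_module_size Number of miRNAs in the condition-specific
#'   co-expression module.
#' @param dc_rho Target within-module correlation in the positive condition
#'   (the module is uncorrelated in the negative condition).
#' @param signature_size Planted overlap of the DE and module sets; must not
#'   exceed `min(n_de, dc_module_size)`.
#' @param n_targets_per_sig mRNAs negatively coupled to each signature miRNA.
#' @param target_rho Target (negative) miRNA-mRNA Spearman correlation.
#' @param label_noise Probability that an observed label is flipped relative
#'   to the true condition; must lie in `[0, 0.5)`.
#' @param library_size_range Length-2 numeric, uniform range of per-sample
#'   total counts.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param test_fraction_or_counts Either a fraction in `(0, 1)` of labeled
#'   samples held out as the external test cohort (stratified by condition),
#'   or an integer vector `c(n_pos_test, n_neg_test)` of exact test counts.
#'   `0` puts every sample in the training split.
#' @param clinical_or Odds ratio linking each clinical covariate to the
#'   observed label (see [generate_cohort()]).
#' @param test_mean_shift Log2 mean shift applied to all features of the
#'   test-cohort samples, emulating a cohort effect (default 0: the external
#'   test set is a held-out split of the same generative process).
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   byte-identically.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_pos = 328L, n_neg = 110L, n_unknown = 14L,
                          n_mirnas = 300L, n_genes = 2000L,
                          n_de = 20L, de_log2fc_range = c(0.8, 2),
                          dc_module_size = 10L, dc_rho = 0.7,
                          signature_size = 7L, n_targets_per_sig = 20L,
                          target_rho = -0.6, label_noise = 0.05,
                          library_size_range = c(5e5, 2e6),
                          nb_dispersion = 0.15,
                          test_fraction_or_counts = 0.2,
                          clinical_or = 3, test_mean_shift = 0,
                          seed = 1L) {
  cfg <- list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    n_unknown = as.integer(n_unknown), n_mirnas = as.integer(n_mirnas),
    n_genes = as.integer(n_genes), n_de = as.integer(n_de),
    de_log2fc_range = as.numeric(de_log2fc_range),
    dc_module_size = as.integer(dc_module_size), dc_rho = dc_rho,
    signature_size = as.integer(signature_size),
    n_targets_per_sig = as.integer(n_targets_per_sig),
    target_rho = target_rho, label_noise = label_noise,
    library_size_range = as.numeric(library_size_range),
    nb_dispersion = nb_dispersion,
    test_fraction_or_counts = test_fraction_or_counts,
    clinical_or = clinical_or, test_mean_shift = test_mean_shift,
    seed = as.integer(seed))

  counts <- c("n_pos", "n_neg", "n_unknown", "n_mirnas", "n_genes", "n_de",
              "dc_module_size", "signature_size", "n_targets_per_sig")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("configuration error: '", f, "' must be a non-negative count")
  }
  if (cfg$signature_size > min(cfg$n_de, cfg$dc_module_size))
    stop("configuration error: signature_size (", cfg$signature_size,
         ") exceeds min(n_de, dc_module_size) = ",
         min(cfg$n_de, cfg$dc_module_size))
  if (cfg$n_pos + cfg$n_neg < 10L)
    stop("configuration error: n_pos + n_neg must be at least 10 ",
         "(two samples per fold for 5-fold cross-validation)")
  if (cfg$label_noise < 0 || cfg$label_noise >= 0.5)
    stop("configuration error: label_noise must lie in [0, 0.5)")
  if (length(cfg$de_log2fc_range) != 2L ||
      cfg$de_log2fc_range[1] > cfg$de_log2fc_range[2] ||
      any(cfg$de_log2fc_range < 0))
    stop("configuration error: de_log2fc_range must be 0 <= low <= high")
  if (cfg$target_rho >= 0 || cfg$target_rho < -1)
    stop("configuration error: target_rho must lie in [-1, 0)")
  if (abs(cfg$dc_rho) >= 1)
    stop("configuration error: |dc_rho| must be < 1")
  if (length(cfg$library_size_range) != 2L ||
      any(cfg$library_size_range <= 0) ||
      cfg$library_size_range[1] > cfg$library_size_range[2])
    stop("configuration error: library_size_range must be 0 < low <= high")
  if (cfg$nb_dispersion < 0)
    stop("configuration error: nb_dispersion must be >= 0")
  tf <- cfg$test_fraction_or_counts
  ok <- (length(tf) == 1L && tf >= 0 && tf < 1) ||
    (length(tf) == 2L && all(tf >= 0) && tf[1] <= cfg$n_pos &&
       tf[2] <= cfg$n_neg)
  if (!ok)
    stop("configuration error: test_fraction_or_counts must be a fraction ",
         "in [0, 1) or c(n_pos_test, n_neg_test) within the class counts")
  if (cfg$n_genes > 0 &&
      cfg$n_targets_per_sig * cfg$signature_size > cfg$n_genes)
    stop("configuration error: n_targets_per_sig * signature_size exceeds ",
         "n_genes")
  structure(cfg, class = "cohort_config")
}

# per-feature sd of log2 counts under the NB model (delta method)
.log2_noise_sd <- function(mu, dispersion) {
  sqrt(1 / pmax(mu, 1e-8) + dispersion) / log(2)
}

.draw_counts <- function(log2_mu, dispersion) {
  mu <- 2^log2_mu
  n <- length(mu)
  x <- if (dispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  } else {
    stats::rpois(n, lambda = mu)
  }
  matrix(as.numeric(x), nrow = nrow(log2_mu), ncol = ncol(log2_mu),
         dimnames = dimnames(log2_mu))
}

# proportional-odds shift of an ordinal probability vector by odds ratio `or`
.po_shift <- function(p, or) {
  cum <- rev(cumsum(rev(p)))          # P(X >= k)
  odds <- cum / (1 - cum)
  cum2 <- ifelse(is.finite(odds), or * odds / (1 + or * odds), 1)
  p2 <- cum2 - c(cum2[-1], 0)
  pmax(p2, 0) / sum(pmax(p2, 0))
}

#' Generate a synthetic train + external-test cohort with ground truth
#'
#' Draws miRNA (and optionally mRNA) negative-binomial count matrices,
#' a sample annotation table and a ground-truth record under the generative
#' model described in the package vignette:
#'
#' * Feature baseline means are log-normal (meanlog 3, sdlog 1.5) on the
#'   reads-per-million scale, rescaled to each sample's library size.
#' * Planted DE miRNAs have their positive-condition mean multiplied by
#'   `2^lfc` with `|lfc|` uniform in `de_log2fc_range` and random sign.
#' * The differential co-expression module shares a per-sample latent factor
#'   added on the log2 scale in the positive condition only, with a
#'   mean-preserving correction, so within-module correlation is about
#'   `dc_rho` in the positive condition and about 0 in the negative one.
#' * Planted target genes couple their latent log2 mean to the realized
#'   (standardized) log2 RPM of their signature miRNA through a Gaussian
#'   copula at correlation `target_rho`.
#' * The observed label equals the condition flipped with probability
#'   `label_noise`; clinical covariates (sample type, AJCC T stage, AJCC
#'   stage) are tilted towards the observed label at odds ratio
#'   `clinical_or` by a proportional-odds shift, with a small rate of
#'   missing stage codes.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `mirna_cohort` with elements
#'   \describe{
#'     \item{mirna}{numeric matrix of miRNA counts, features x samples.}
#'     \item{mrna}{numeric matrix of mRNA counts, or `NULL`.}
#'     \item{annotation}{data.frame with columns `sample_id`, `label`,
#'       `sample_type`, `ajcc_t`, `ajcc_stage`, `split`.}
#'     \item{truth}{ground-truth record: planted DE ids with signed log2FC,
#'       module ids, signature ids, target links, the true condition per
#'       sample and a description of the label rule.}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_pos = 30, n_neg = 20,
#'   n_unknown = 0, n_mirnas = 50, n_genes = 0, n_de = 5,
#'   dc_module_size = 4, signature_size = 3, n_targets_per_sig = 0,
#'   seed = 7))
#' dim(cohort$mirna)
#' table(cohort$annotation$label)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  with(config, {
    n_lab <- n_pos + n_neg
    n <- n_lab + n_unknown
    sample_ids <- sprintf("S%04d", seq_len(n))
    mir_ids <- sprintf("mir-%03d", seq_len(n_mirnas))

    # unknown status is independent of condition; exact class counts hold
    # among the labeled samples
    is_unknown <- seq_len(n) %in% sample(n, n_unknown)
    cond_lab <- c(rep("positive", n_pos), rep("negative", n_neg))
    cond_lab <- cond_lab[sample(n_lab)]
    cond_unk <- sample(c("positive", "negative"), n_unknown, replace = TRUE,
                       prob = c(n_pos, n_neg) / n_lab)
    condition <- character(n)
    condition[!is_unknown] <- cond_lab
    condition[is_unknown] <- cond_unk
    names(condition) <- sample_ids
    pos <- condition == "positive"

    # planted feature sets ------------------------------------------------
    pool <- sample(n_mirnas)
    sig_idx <- pool[seq_len(signature_size)]
    de_idx <- c(sig_idx, pool[signature_size + seq_len(n_de - signature_size)])
    dc_idx <- c(sig_idx, pool[n_de + seq_len(dc_module_size - signature_size)])
    lfc <- stats::runif(n_de, de_log2fc_range[1], de_log2fc_range[2]) *
      sample(c(-1, 1), n_de, replace = TRUE)

    # latent log2 means ----------------------------------------------------
    baseline <- stats::rlnorm(n_mirnas, meanlog = 3, sdlog = 1.5)
    baseline <- baseline / sum(baseline) * 1e6          # RPM scale
    libsize <- stats::runif(n, library_size_range[1], library_size_range[2])
    M <- log2(outer(baseline, libsize) / 1e6)
    dimnames(M) <- list(mir_ids, sample_ids)
    if (n_de > 0 && any(pos))
      M[de_idx, pos] <- M[de_idx, pos] + lfc
    if (dc_module_size > 1 && any(pos)) {
      mu_mod <- baseline[dc_idx] / 1e6 * mean(libsize)
      s_mod <- .log2_noise_sd(mu_mod, nb_dispersion)
      lambda <- s_mod * sqrt(dc_rho / (1 - dc_rho))
      f <- stats::rnorm(sum(pos))
      M[dc_idx, pos] <- M[dc_idx, pos] + outer(lambda, f) -
        lambda^2 * log(2) / 2   # keep marginal means unchanged
    }

    # split ----------------------------------------------------------------
    split <- rep("train", n)
    tf <- test_fraction_or_counts
    idx_pos <- which(pos & !is_unknown)
    idx_neg <- which(!pos & !is_unknown)
    n_test <- if (length(tf) == 2L) round(tf) else round(tf * c(n_pos, n_neg))
    if (sum(n_test) > 0) {
      split[sample(idx_pos, n_test[1])] <- "test"
      split[sample(idx_neg, n_test[2])] <- "test"
    }
    if (test_mean_shift != 0)
      M[, split == "test"] <- M[, split == "test"] + test_mean_shift

    mirna <- .draw_counts(M, nb_dispersion)

    # labels & clinical ------------------------------------------------------
    label <- condition
    flip <- stats::runif(n) < label_noise
    label[flip] <- ifelse(condition[flip] == "positive", "negative", "positive")
    label[is_unknown] <- "unknown"
    lab_eff <- ifelse(is_unknown, condition, label)  # clinical sees outcome
    or_vec <- ifelse(lab_eff == "positive", clinical_or, 1)

    p_met_neg <- 0.65                     # baseline P(metastatic | negative)
    odds <- p_met_neg / (1 - p_met_neg) * or_vec
    sample_type <- ifelse(stats::runif(n) < odds / (1 + odds),
                          "metastatic", "primary")
    p_t <- c(0.35, 0.30, 0.20, 0.15)      # T1..T4 baseline
    p_stage <- c(0.25, 0.30, 0.30, 0.15)  # I..IV baseline
    ajcc_t <- vapply(or_vec, function(o)
      paste0("T", sample(4, 1, prob = .po_shift(p_t, o))), character(1))
    ajcc_stage <- vapply(or_vec, function(o)
      c("I", "II", "III", "IV")[sample(4, 1, prob = .po_shift(p_stage, o))],
      character(1))
    ajcc_t[stats::runif(n) < 0.05] <- "TX"
    ajcc_stage[stats::runif(n) < 0.05] <- "missing"

    annotation <- data.frame(
      sample_id = sample_ids, label = unname(label),
      sample_type = unname(sample_type), ajcc_t = unname(ajcc_t),
      ajcc_stage = unname(ajcc_stage), split = split,
      stringsAsFactors = FALSE)
    rownames(annotation) <- NULL

    # mRNA matrix with planted negative coupling ----------------------------
    mrna <- NULL
    target_links <- data.frame(mirna_id = character(0), gene_id = character(0),
                               rho = numeric(0), stringsAsFactors = FALSE)
    if (n_genes > 0) {
      gene_ids <- sprintf("gene-%04d", seq_len(n_genes))
      gb <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1.5)
      n_t <- n_targets_per_sig * signature_size
      gpool <- sample(n_genes)
      if (n_t > 0) {
        planted_g <- gpool[seq_len(n_t)]
        # planted targets are drawn moderately expressed so the coupling is
        # observable at sequencing depth
        gb[planted_g] <- stats::rlnorm(n_t, meanlog = 4, sdlog = 0.8)
      }
      gb <- gb / sum(gb) * 1e6
      lib_g <- stats::runif(n, library_size_range[1], library_size_range[2])
      G <- log2(outer(gb, lib_g) / 1e6)
      dimnames(G) <- list(gene_ids, sample_ids)
      if (n_t > 0) {
        rpm_mir <- sweep(mirna, 2, colSums(mirna), "/") * 1e6
        s_g <- 1.5                       # latent log2 sd of the coupling
        for (k in seq_len(signature_size)) {
          z <- log2(rpm_mir[sig_idx[k], ] + 1)
          z <- (z - mean(z)) / max(stats::sd(z), 1e-8)
          g_k <- planted_g[(k - 1) * n_targets_per_sig +
                             seq_len(n_targets_per_sig)]
          for (g in g_k) {
            u <- target_rho * z +
              sqrt(1 - target_rho^2) * stats::rnorm(n)
            G[g, ] <- G[g, ] + s_g * u - s_g^2 * log(2) / 2
          }
          target_links <- rbind(target_links, data.frame(
            mirna_id = mir_ids[sig_idx[k]], gene_id = gene_ids[g_k],
            rho = target_rho, stringsAsFactors = FALSE))
        }
      }
      mrna <- .draw_counts(G, nb_dispersion)
    }

    truth <- list(
      de_ids = data.frame(feature_id = mir_ids[de_idx], log2fc = lfc,
                          stringsAsFactors = FALSE),
      dc_ids = sort(mir_ids[dc_idx]),
      signature_ids = sort(mir_ids[sig_idx]),
      target_links = target_links,
      condition = data.frame(sample_id = sample_ids,
                             condition = unname(condition),
                             stringsAsFactors = FALSE),
      label_rule = paste0(
        "observed label = true condition flipped with probability ",
        label_noise, "; condition assigned with exact class counts ",
        n_pos, "/", n_neg))

    structure(list(mirna = mirna, mrna = mrna, annotation = annotation,
                   truth = truth, config = config),
              class = "mirna_cohort")
  })
}

#' @export
print.mirna_cohort <- function(x, ...) {
  cat("Synthetic miRNA-Seq cohort\n")
  cat("  miRNAs:", nrow(x$mirna), " samples:", ncol(x$mirna), "\n")
  if (!is.null(x$mrna)) cat("  mRNAs: ", nrow(x$mrna), "\n")
  cat("  labels:", paste(names(table(x$annotation$label)),
                         table(x$annotation$label), collapse = ", "), "\n")
  cat("  planted signature:", paste(x$truth$signature_ids, collapse = ", "),
      "\n")
  invisible(x)
}
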