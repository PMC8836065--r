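.label_vocab <- c("positive", "negative", "unknown")
.split_vocab <- c("train", "test")
.type_vocab <- c("primary", "metastatic")
.t_vocab <- c("Tis", "T0", "T1", "T2", "T3", "T4", "TX", "missing")
.stage_vocab <- c("I", "II", "III", "IV", "missing")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_count_matrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

.read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "feature_id")
    stop("parse error in ", path, ": first column must be 'feature_id'")
  sample_ids <- names(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("parse error in ", path, ": duplicated sample column '",
         sample_ids[duplicated(sample_ids)][1], "'")
  if (anyDuplicated(df$feature_id))
    stop("parse error in ", path, ": duplicated feature id '",
         df$feature_id[duplicated(df$feature_id)][1], "'")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat))
    stop("parse error in ", path, ": non-numeric counts")
  bad <- which(is.na(mat) | mat < 0 | mat != floor(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("parse error in ", path, ": non-integer or negative count at row '",
         df$feature_id[bad[1, 1]], "', column '", sample_ids[bad[1, 2]], "'")
  rownames(mat) <- df$feature_id
  mat
}

.check_vocab <- function(x, vocab, column, path) {
  bad <- setdiff(unique(x), vocab)
  if (length(bad) > 0)
    stop("parse error in ", path, ": column '", column, "' contains '",
         bad[1], "'; allowed values: ", paste(vocab, collapse = ", "))
}

#' Write / read a cohort to and from plain-text files
#'
#' `write_cohort()` serializes a cohort as TSV count matrices
#' (`mirna.tsv`, `mrna.tsv`; first column `feature_id`, remaining columns
#' one per sample), a TSV annotation table (`annotation.tsv`) and a JSON
#' ground-truth record (`truth.json`). `read_cohort()` reads the same
#' layout back, validating ids, vocabularies and count integrality; the
#' round trip is exact.
#'
#' @param dir Directory to write to / read from (created if needed).
#' @param cohort A `mirna_cohort` from [generate_cohort()] (or the same
#'   shape assembled by hand).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `mirna_cohort` list.
#' @export
write_cohort <- function(dir, cohort) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_count_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  if (!is.null(cohort$mrna))
    .write_count_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  .write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mirna <- .read_count_matrix(file.path(dir, "mirna.tsv"))
  mrna_path <- file.path(dir, "mrna.tsv")
  mrna <- if (file.exists(mrna_path)) .read_count_matrix(mrna_path) else NULL
  ann_path <- file.path(dir, "annotation.tsv")
  annotation <- utils::read.delim(ann_path, stringsAsFactors = FALSE,
                                  colClasses = "character")
  need <- c("sample_id", "label", "sample_type", "ajcc_t", "ajcc_stage",
            "split")
  miss <- setdiff(need, names(annotation))
  if (length(miss) > 0)
    stop("parse error in ", ann_path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$sample_id))
    stop("parse error in ", ann_path, ": duplicated sample_id '",
         annotation$sample_id[duplicated(annotation$sample_id)][1], "'")
  .check_vocab(annotation$label, .label_vocab, "label", ann_path)
  .check_vocab(annotation$split, .split_vocab, "split", ann_path)
  .check_vocab(annotation$sample_type, .type_vocab, "sample_type", ann_path)
  .check_vocab(annotation$ajcc_t, .t_vocab, "ajcc_t", ann_path)
  .check_vocab(annotation$ajcc_stage, .stage_vocab, "ajcc_stage", ann_path)
  if (!setequal(annotation$sample_id, colnames(mirna)))
    stop("parse error: annotation sample_ids do not match mirna.tsv columns")
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path))
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  structure(list(mirna = mirna, mrna = mrna, annotation = annotation,
                 truth = truth, config = NULL),
            class = "mirna_cohort")
}
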