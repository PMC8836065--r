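.encode_ajcc_t <- function(x) {
  map <- c(Tis = 0, T0 = 0, T1 = 1, T2 = 2, T3 = 3, T4 = 4)
  out <- unname(map[x])          # TX / missing -> NA
  out
}

.encode_ajcc_stage <- function(x) {
  # strip letter sub-stages (IIIA -> III) before mapping I..IV -> 1..4
  core <- sub("^((IV)|(III)|(II)|(I)).*$", "\\1", x)
  map <- c(I = 1, II = 2, III = 3, IV = 4)
  unname(map[core])
}

#' Assemble the classifier feature table
#'
#' Builds a samples x features numeric matrix from the signature miRNAs'
#' `log2(RPM + 1)` values, optionally appending encoded clinical
#' covariates: `sample_type` (primary 0 / metastatic 1), AJCC T stage as an
#' ordinal (Tis, T0 -> 0; T1..T4 -> 1..4; TX or missing imputed with the
#' training-split median) and AJCC stage as an ordinal (I..IV -> 1..4,
#' letter sub-stages ignored; missing imputed likewise). All columns are
#' z-scored with means and standard deviations computed on the training
#' split only and applied unchanged to the test split; samples with
#' unknown labels are dropped.
#'
#' @param rpm miRNA RPM matrix covering train and test samples.
#' @param signature A `mirna_signature` or character vector of feature ids.
#' @param annotation Sample annotation with labels, clinical fields, split.
#' @param clinical One of `"none"`, `"all"`, `"sample_type"`, `"ajcc_t"`,
#'   `"ajcc_stage"`.
#' @return Object of class `feature_table`: list with `x` (matrix), `y`
#'   (factor negative/positive), `split`, `sample_ids`, `scaler`.
#' @export
build_feature_table <- function(rpm, signature, annotation,
                                clinical = c("none", "all", "sample_type",
                                             "ajcc_t", "ajcc_stage")) {
  clinical <- match.arg(clinical)
  ids <- if (inherits(signature, "mirna_signature")) signature$feature_ids
         else as.character(signature)
  missing_ids <- setdiff(ids, rownames(rpm))
  if (length(missing_ids) > 0)
    stop("signature feature(s) absent from expression matrix: ",
         paste(missing_ids, collapse = ", "))
  ann <- annotation[match(colnames(rpm), annotation$sample_id), ]
  keep <- ann$label %in% c("positive", "negative")
  ann <- ann[keep, ]
  x <- t(log2(rpm[ids, keep, drop = FALSE] + 1))
  colnames(x) <- ids
  if (clinical != "none") {
    cols <- list()
    if (clinical %in% c("all", "sample_type"))
      cols$sample_type <- as.numeric(ann$sample_type == "metastatic")
    if (clinical %in% c("all", "ajcc_t"))
      cols$ajcc_t <- .encode_ajcc_t(ann$ajcc_t)
    if (clinical %in% c("all", "ajcc_stage"))
      cols$ajcc_stage <- .encode_ajcc_stage(ann$ajcc_stage)
    clin <- do.call(cbind, cols)
    train <- ann$split == "train"
    for (j in seq_len(ncol(clin))) {           # train-median imputation
      med <- stats::median(clin[train, j], na.rm = TRUE)
      clin[is.na(clin[, j]), j] <- med
    }
    x <- cbind(x, clin)
  }
  train <- ann$split == "train"
  center <- colMeans(x[train, , drop = FALSE])
  scale_ <- apply(x[train, , drop = FALSE], 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  structure(list(
    x = x,
    y = factor(ann$label, levels = c("negative", "positive")),
    split = ann$split,
    sample_ids = ann$sample_id,
    scaler = list(center = center, scale = scale_)),
    class = "feature_table")
}
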