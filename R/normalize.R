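#' Reads-per-million normalization
#'
#' Scales every sample (column) so its total is one million:
#' `rpm[i, s] = counts[i, s] / colsum[s] * 1e6`. RPM is the expression
#' scale used throughout the pipeline, including as classifier input.
#'
#' @param counts Numeric matrix, features x samples, non-negative.
#' @return Matrix of the same shape on the RPM scale.
#' @export
compute_rpm <- function(counts) {
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    bad <- colnames(counts)[which(cs <= 0)[1]]
    if (is.null(bad)) bad <- which(cs <= 0)[1]
    stop("sample '", bad, "' has zero total counts; cannot normalize")
  }
  sweep(counts, 2, cs, "/") * 1e6
}

#' Remove features below an expression floor
#'
#' Retains features with RPM at or above `min_rpm` in at least
#' `min_fraction` of samples; row order is preserved. The default
#' (RPM >= 1 in >= 10\% of samples) removes all-zero and noise-level
#' features ahead of testing.
#'
#' @param rpm RPM matrix from [compute_rpm()].
#' @param min_rpm Expression floor on the RPM scale.
#' @param min_fraction Minimum fraction of samples at or above the floor.
#' @return The filtered RPM matrix (possibly with zero rows).
#' @export
filter_low_expression <- function(rpm, min_rpm = 1, min_fraction = 0.1) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  keep <- rowMeans(rpm >= min_rpm) >= min_fraction
  if (!any(keep))
    message("filter_low_expression: no features pass the filter")
  rpm[keep, , drop = FALSE]
}

.condition_of <- function(rpm, annotation) {
  lab <- annotation$label[match(colnames(rpm), annotation$sample_id)]
  if (anyNA(lab))
    stop("annotation is missing sample(s): ",
         paste(utils::head(colnames(rpm)[is.na(lab)], 3), collapse = ", "))
  lab
}

#' Per-feature log2 fold change between conditions
#'
#' `log2((mean_pos + pseudocount) / (mean_neg + pseudocount))` of group mean
#' RPM, positive condition (recurrent / metastatic) over negative, for each
#' feature. Samples with unknown labels are excluded.
#'
#' @param rpm RPM matrix.
#' @param annotation Sample annotation with `sample_id` and `label`.
#' @param pseudocount Added to both group means before the ratio (default 1
#'   on the RPM scale, keeping zeros finite).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(rpm, annotation, pseudocount = 1) {
  lab <- .condition_of(rpm, annotation)
  if (!any(lab == "positive") || !any(lab == "negative"))
    stop("both conditions must have at least one sample")
  m_pos <- rowMeans(rpm[, lab == "positive", drop = FALSE])
  m_neg <- rowMeans(rpm[, lab == "negative", drop = FALSE])
  log2((m_pos + pseudocount) / (m_neg + pseudocount))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: `padj_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1 and returned in the input order. Controls the false
#' discovery rate at the chosen cutoff.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  adj <- pmin(1, cummin(rev(pvalues[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- rev(adj)
  out
}

#' Differential expression testing on log2 RPM
#'
#' Tests each feature for a location shift between the positive and
#' negative conditions on `log2(RPM + pseudocount)`: two-sided
#' Mann-Whitney U by default (distribution-free), or Welch's t as a
#' configurable alternative. P-values are BH-adjusted; a feature is
#' `significant` when `padj < alpha`.
#'
#' @param rpm RPM matrix (typically after [filter_low_expression()]).
#' @param annotation Sample annotation; unknown-label samples are excluded.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param test `"wilcoxon"` (default) or `"welch"`.
#' @param pseudocount Pseudocount for the log transform and fold change.
#' @return data.frame of class `de_results` with columns `feature_id`,
#'   `log2fc`, `pvalue`, `padj`, `significant`, sorted by `padj` then
#'   feature id.
#' @export
differential_expression <- function(rpm, annotation, alpha = 0.05,
                                    test = c("wilcoxon", "welch"),
                                    pseudocount = 1) {
  test <- match.arg(test)
  lab <- .condition_of(rpm, annotation)
  keep <- lab != "unknown"
  rpm <- rpm[, keep, drop = FALSE]
  lab <- lab[keep]
  if (sum(lab == "positive") < 3 || sum(lab == "negative") < 3)
    stop("each condition needs at least 3 samples for testing")
  lx <- log2(rpm + pseudocount)
  a <- lab == "positive"
  pv <- apply(lx, 1, function(v) {
    if (stats::sd(v) == 0) return(1)
    if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(v[a], v[!a], exact = FALSE)$p.value)
    } else {
      stats::t.test(v[a], v[!a])$p.value
    }
  })
  pv[is.na(pv)] <- 1
  res <- data.frame(
    feature_id = rownames(rpm),
    log2fc = unname(log2_fold_change(rpm, annotation, pseudocount)),
    pvalue = unname(pv),
    padj = benjamini_hochberg(unname(pv)),
    stringsAsFactors = FALSE)
  res$significant <- res$padj < alpha
  res <- res[order(res$padj, res$feature_id), ]
  rownames(res) <- NULL
  class(res) <- c("de_results", "data.frame")
  res
}
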