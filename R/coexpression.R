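# Spearman correlation matrix of the rows of X (features x samples).
# Zero-variance rows get correlation 0 with everything.
.spearman_rows <- function(X) {
  r <- t(apply(X, 1, rank))
  rs <- r - rowMeans(r)
  nrm <- sqrt(rowSums(rs^2))
  nz <- nrm > 0
  rs[nz, ] <- rs[nz, , drop = FALSE] / nrm[nz]
  rs[!nz, ] <- 0
  C <- tcrossprod(rs)
  C[C > 1] <- 1
  C[C < -1] <- -1
  C
}

.fisher_z <- function(rho, clip = 0.999) atanh(pmax(pmin(rho, clip), -clip))

.shift_from_groups <- function(X, in_a) {
  as.numeric(.cpp_shift_scores(X, as.logical(in_a)))
}

#' Build a within-condition miRNA co-expression network
#'
#' Nodes are features; an edge joins features i and j when their Spearman
#' correlation across the condition's samples satisfies `|rho| >= tau` and
#' its BH-adjusted p-value (t approximation) is below `edge_alpha`.
#'
#' @param rpm RPM matrix.
#' @param annotation Sample annotation with `sample_id` and `label`.
#' @param condition `"positive"` or `"negative"`.
#' @param tau Absolute-correlation edge threshold (default 0.6).
#' @param edge_alpha BH-adjusted p cutoff for edges (default 0.05).
#' @return List of class `coexpression_network` with `condition`, `nodes`
#'   and an `edges` data.frame (`feature_a`, `feature_b`, `rho`, `pvalue`,
#'   `padj`), each unordered pair stored once.
#' @export
build_network <- function(rpm, annotation, condition, tau = 0.6,
                          edge_alpha = 0.05) {
  lab <- .condition_of(rpm, annotation)
  if (!condition %in% lab)
    stop("condition '", condition, "' absent from annotation")
  X <- rpm[, lab == condition, drop = FALSE]
  n <- ncol(X)
  if (n < 5) stop("need at least 5 samples in condition '", condition, "'")
  C <- .spearman_rows(X)
  ut <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[ut]
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pv[abs(rho) >= 1] <- 0
  padj <- benjamini_hochberg(pv)
  keep <- abs(rho) >= tau & padj < edge_alpha
  edges <- data.frame(
    feature_a = rownames(rpm)[ut[keep, 1]],
    feature_b = rownames(rpm)[ut[keep, 2]],
    rho = rho[keep], pvalue = pv[keep], padj = padj[keep],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$feature_a, edges$feature_b), ]
  rownames(edges) <- NULL
  structure(list(condition = condition, nodes = rownames(rpm),
                 edges = edges, tau = tau, edge_alpha = edge_alpha),
            class = "coexpression_network")
}

#' Fisher-z connectivity-shift scores
#'
#' For each feature i, the shift statistic is
#' `sum_j |z(rho_pos(i, j)) - z(rho_neg(i, j))|` over all other features j,
#' where rho is the within-condition Spearman correlation and z the Fisher
#' transform clipped at `|rho| <= 0.999`. The score is non-negative, zero
#' when the two conditions' correlation rows coincide, and invariant under
#' strictly monotone per-feature transforms of the expression values.
#'
#' @param rpm RPM matrix with at least 2 features.
#' @param annotation Sample annotation; both conditions need >= 5 samples.
#' @return data.frame with columns `feature_id` and `score`.
#' @export
connectivity_shift_scores <- function(rpm, annotation) {
  if (nrow(rpm) < 2) stop("need at least 2 features")
  lab <- .condition_of(rpm, annotation)
  keep <- lab != "unknown"
  X <- rpm[, keep, drop = FALSE]
  lab <- lab[keep]
  if (sum(lab == "positive") < 5 || sum(lab == "negative") < 5)
    stop("both conditions need at least 5 samples")
  data.frame(feature_id = rownames(rpm),
             score = unname(.shift_from_groups(X, lab == "positive")),
             stringsAsFactors = FALSE)
}

#' Permutation significance of connectivity shifts
#'
#' Recomputes the shift score of every feature under `n_perm` random
#' permutations of the condition labels (group sizes preserved; one shared
#' shuffled-label sequence per permutation across all features, preserving
#' the feature dependence structure). The add-one permutation p-value
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)` is BH-adjusted and a
#' feature is flagged `altered` when `padj < alpha`.
#'
#' With `prune = TRUE` (the default), features whose exceedance count
#' already guarantees an unadjusted p above `alpha` stop being scored:
#' the count is non-decreasing, so once `(1 + count) / (n_perm + 1) >
#' alpha` the feature can never be called altered (`padj >= pvalue`).
#' Pruned features report the valid permutation p-value from the
#' permutations they did see, at correspondingly coarser resolution; the
#' set of `altered` calls is identical to an exhaustive run, because a
#' pruned feature's p-value exceeds `alpha` either way and cannot change
#' the BH step-up decision for the features below the cutoff. Set
#' `prune = FALSE` for exhaustive scoring (e.g. when the full null
#' distribution of every feature is of interest).
#'
#' Resolution note: the smallest attainable p is `1/(n_perm + 1)`, so with
#' `m` features BH can only flag a group of `k` floor-level features when
#' `n_perm >= m / (k * alpha)`; choosing `n_perm >= m / (2 * alpha)`
#' makes a minimal two-feature module resolvable.
#'
#' @param rpm RPM matrix.
#' @param annotation Sample annotation.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha BH-adjusted significance cutoff.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param prune Stop scoring features that can no longer reach
#'   significance (default `TRUE`; see Details).
#' @return data.frame of class `connectivity_shifts` with columns
#'   `feature_id`, `score`, `pvalue`, `padj`, `altered`.
#' @export
permutation_significance <- function(rpm, annotation, n_perm = 1000,
                                     alpha = 0.05, seed = 1L,
                                     prune = TRUE) {
  stopifnot(n_perm >= 100)
  if (nrow(rpm) < 2) stop("need at least 2 features")
  lab <- .condition_of(rpm, annotation)
  keep <- lab != "unknown"
  X <- rpm[, keep, drop = FALSE]
  lab <- lab[keep]
  if (sum(lab == "positive") < 5 || sum(lab == "negative") < 5)
    stop("both conditions need at least 5 samples")
  in_a <- lab == "positive"
  obs <- .shift_from_groups(X, in_a)
  set.seed(seed)
  perms <- t(vapply(seq_len(n_perm), function(b) as.integer(sample(in_a)),
                    integer(length(in_a))))
  cap <- if (prune) alpha * (n_perm + 1) - 1 else -1
  res_cpp <- .cpp_perm_counts(X, perms, obs, cap)
  pv <- (1 + res_cpp$count) / (res_cpp$done + 1)
  padj <- benjamini_hochberg(pv)
  res <- data.frame(feature_id = rownames(rpm), score = unname(obs),
                    pvalue = unname(pv), padj = unname(padj),
                    altered = unname(padj < alpha),
                    stringsAsFactors = FALSE)
  class(res) <- c("connectivity_shifts", "data.frame")
  res
}
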