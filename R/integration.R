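#' Negatively correlated miRNA-mRNA pairs
#'
#' Computes the Spearman correlation between every signature miRNA and
#' every gene across the shared samples and keeps pairs with
#' `rho < rho_threshold` (default -0.25), the negative-correlation filter
#' used to nominate putative targets. mRNA input may be raw counts (then
#' RPM-normalized like the miRNAs) or pre-normalized values; the rank
#' correlation is unaffected by that monotone choice.
#'
#' @param mirna_rpm miRNA RPM matrix.
#' @param mrna_expr mRNA matrix (counts or normalized), genes x samples.
#' @param signature A `mirna_signature` or character vector of miRNA ids.
#' @param rho_threshold Keep pairs strictly below this (negative) value.
#' @param mrna_is_counts If `TRUE` (default) normalize `mrna_expr` to RPM.
#' @return data.frame of class `correlation_pairs` with columns `mirna_id`,
#'   `gene_id`, `rho`, `kept`, sorted by `rho` ascending.
#' @export
negative_correlation_pairs <- function(mirna_rpm, mrna_expr, signature,
                                       rho_threshold = -0.25,
                                       mrna_is_counts = TRUE) {
  ids <- if (inherits(signature, "mirna_signature")) signature$feature_ids
         else as.character(signature)
  if (length(ids) == 0) stop("signature is empty")
  missing_ids <- setdiff(ids, rownames(mirna_rpm))
  if (length(missing_ids) > 0)
    stop("signature feature(s) absent from miRNA matrix: ",
         paste(missing_ids, collapse = ", "))
  shared <- intersect(colnames(mirna_rpm), colnames(mrna_expr))
  if (length(shared) == 0) stop("no shared samples between the matrices")
  A <- mirna_rpm[ids, shared, drop = FALSE]
  B <- mrna_expr[, shared, drop = FALSE]
  if (mrna_is_counts) B <- compute_rpm(B)
  rho <- stats::cor(t(A), t(B), method = "spearman")
  pairs <- data.frame(
    mirna_id = rep(ids, times = ncol(rho)),
    gene_id = rep(colnames(rho), each = length(ids)),
    rho = as.vector(rho),
    stringsAsFactors = FALSE)
  pairs$kept <- pairs$rho < rho_threshold
  pairs <- pairs[order(pairs$rho, pairs$mirna_id, pairs$gene_id), ]
  rownames(pairs) <- NULL
  attr(pairs, "rho_threshold") <- rho_threshold
  class(pairs) <- c("correlation_pairs", "data.frame")
  pairs
}

#' Top anti-correlated putative target genes
#'
#' Ranks kept genes by their most negative correlation with any signature
#' miRNA and returns the `k` strongest (ties broken by gene id); fewer than
#' `k` kept genes returns them all.
#'
#' @param pairs Output of [negative_correlation_pairs()].
#' @param k Number of genes to return (>= 1).
#' @return data.frame with columns `gene_id` and `rho`.
#' @export
top_anticorrelated <- function(pairs, k = 20) {
  stopifnot(k >= 1)
  kept <- pairs[pairs$kept, , drop = FALSE]
  if (nrow(kept) == 0)
    return(data.frame(gene_id = character(0), rho = numeric(0),
                      stringsAsFactors = FALSE))
  best <- tapply(kept$rho, kept$gene_id, min)
  out <- data.frame(gene_id = names(best), rho = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rho, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Common putative targets of two signatures
#'
#' Genes whose pairs are kept (negatively correlated past the threshold)
#' in both contexts, e.g. the recurrence and the metastasis signature.
#'
#' @param pairs_a,pairs_b Two [negative_correlation_pairs()] results.
#' @return Sorted character vector of gene ids.
#' @export
common_targets <- function(pairs_a, pairs_b) {
  sort(intersect(unique(pairs_a$gene_id[pairs_a$kept]),
                 unique(pairs_b$gene_id[pairs_b$kept])))
}

#' Restrict correlation pairs to a user-supplied target map
#'
#' Target prediction itself (sequence-based, external databases) is out of
#' scope; this consumes a pre-computed two-column TSV mapping
#' (`mirna_id`, `gene_id`) and keeps only listed combinations, leaving
#' `rho` and `kept` untouched.
#'
#' @param pairs Output of [negative_correlation_pairs()].
#' @param target_map_file Path to the two-column TSV.
#' @return The filtered pairs data.frame.
#' @export
restrict_to_target_map <- function(pairs, target_map_file) {
  map <- utils::read.delim(target_map_file, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("mirna_id", "gene_id") %in% names(map)))
    stop("parse error in ", target_map_file,
         ": need columns 'mirna_id' and 'gene_id'")
  if (nrow(map) == 0)
    warning("target map is empty; returning no pairs")
  keys <- paste(map$mirna_id, map$gene_id, sep = "\r")
  out <- pairs[paste(pairs$mirna_id, pairs$gene_id, sep = "\r") %in% keys, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}
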