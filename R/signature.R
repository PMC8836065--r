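#' Intersect differential-expression and connectivity-shift results
#'
#' The signature is the set of features that pass both filters: flagged
#' `significant` in the DE results and `altered` in the connectivity-shift
#' results. Provenance (log2FC, DE adjusted p, shift score, shift adjusted
#' p) is carried for every member; features are ordered by id for
#' determinism.
#'
#' @param de_results Output of [differential_expression()].
#' @param shifts Output of [permutation_significance()].
#' @param context `"recurrence"` or `"metastasis"` (a label carried through
#'   to reports).
#' @return Object of class `mirna_signature`: list with `context`,
#'   `feature_ids` and a `provenance` data.frame.
#' @export
intersect_signature <- function(de_results, shifts,
                                context = c("recurrence", "metastasis")) {
  context <- match.arg(context)
  if (!setequal(de_results$feature_id, shifts$feature_id)) {
    only_de <- setdiff(de_results$feature_id, shifts$feature_id)
    only_sh <- setdiff(shifts$feature_id, de_results$feature_id)
    stop("feature universes differ; only in DE: ",
         paste(utils::head(only_de, 5), collapse = ", "),
         "; only in shifts: ", paste(utils::head(only_sh, 5), collapse = ", "))
  }
  ids <- sort(intersect(de_results$feature_id[de_results$significant],
                        shifts$feature_id[shifts$altered]))
  if (length(ids) == 0)
    warning("empty signature: no feature passes both filters")
  i_de <- match(ids, de_results$feature_id)
  i_sh <- match(ids, shifts$feature_id)
  provenance <- data.frame(
    feature_id = ids,
    log2fc = de_results$log2fc[i_de],
    padj_de = de_results$padj[i_de],
    shift_score = shifts$score[i_sh],
    padj_dc = shifts$padj[i_sh],
    stringsAsFactors = FALSE)
  structure(list(context = context, feature_ids = ids,
                 provenance = provenance),
            class = "mirna_signature")
}

#' @export
print.mirna_signature <- function(x, ...) {
  cat(length(x$feature_ids), "-miRNA ", x$context, " signature: ",
      paste(x$feature_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tabular signature report
#'
#' Returns (and optionally writes) the signature as a table with columns
#' `feature_id`, `log2fc`, `padj` — the layout of a published signature
#' table, using the DE adjusted p-value.
#'
#' @param signature A `mirna_signature`.
#' @param path Optional TSV output path.
#' @return data.frame with one row per signature feature.
#' @export
signature_report <- function(signature, path = NULL) {
  if (length(signature$feature_ids) == 0) {
    message("signature_report: empty signature, nothing to report")
    tab <- data.frame(feature_id = character(0), log2fc = numeric(0),
                      padj = numeric(0), stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(feature_id = signature$provenance$feature_id,
                      log2fc = signature$provenance$log2fc,
                      padj = signature$provenance$padj_de,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) .write_tsv(tab, path)
  tab
}
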