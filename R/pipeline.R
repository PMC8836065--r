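#' Configure an end-to-end pipeline run
#'
#' Collects the per-stage settings of the full chain
#' simulate -> DE -> differential co-expression -> signature ->
#' mRNA integration -> train/evaluate. One master `seed` deterministically
#' derives every stage seed (see [stage_seed()]), so stages can be re-run
#' in isolation and a rerun with the same config reproduces identical
#' summaries.
#'
#' @param cohort A [cohort_config()].
#' @param de List: `alpha`, `test`, `min_rpm`, `min_fraction`.
#' @param dcn List: `tau`, `edge_alpha`, `n_perm`, `alpha`.
#' @param integration List: `rho_threshold`, `top_k`.
#' @param moo List: `population`, `generations`, `folds`, `clinical`
#'   (one of the [build_feature_table()] clinical flags; anything but
#'   `"none"` adds a clinically augmented model alongside the
#'   signature-only one).
#' @param seed Master seed.
#' @param output_dir Run directory (created by [run_pipeline()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            de = list(), dcn = list(), integration = list(),
                            moo = list(), seed = 1L,
                            output_dir = tempfile("mirpareto_run_")) {
  cfg <- list(
    cohort = cohort,
    de = utils::modifyList(list(alpha = 0.05, test = "wilcoxon",
                                min_rpm = 1, min_fraction = 0.1), de),
    dcn = utils::modifyList(list(tau = 0.6, edge_alpha = 0.05,
                                 n_perm = 1000, alpha = 0.05), dcn),
    integration = utils::modifyList(list(rho_threshold = -0.25,
                                         top_k = 20), integration),
    moo = utils::modifyList(list(population = 60, generations = 40,
                                 folds = 5, clinical = "none"), moo),
    seed = as.integer(seed), output_dir = output_dir)
  stopifnot(inherits(cohort, "cohort_config"))
  structure(cfg, class = "pipeline_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic hash of the master seed and the stage name, kept inside
#' the 32-bit integer range, so each stage has an independent, reproducible
#' random stream.
#'
#' @param master Integer master seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483647)
}

.report_as_list <- function(rep) {
  list(acc = rep$acc, sp = rep$sp, sen = rep$sen)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> RPM + filtering -> differential expression ->
#' connectivity-shift permutation test -> signature intersection ->
#' negative-correlation mRNA integration -> multi-objective ensemble
#' training -> CV and external-test evaluation, writing every intermediate
#' table to the run directory together with a machine-readable
#' `summary.json` and a `run.log` with stage timings and seeds. DE, the
#' permutation test and the co-expression networks use the training split
#' only; the test split is touched once, for external evaluation. An empty
#' signature skips the classifier stage and flags the summary.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summary` (the summary.json content),
#'   `cohort`, `signature`, `fronts`, and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    log_line("stage %-10s done in %.1fs", stage,
             proc.time()[["elapsed"]] - t0)
    res
  }

  # 1. simulate ------------------------------------------------------------
  ccfg <- config$cohort
  ccfg$seed <- stage_seed(config$seed, "cohort")
  log_line("stage cohort     seed %d", ccfg$seed)
  cohort <- timed("cohort", generate_cohort(ccfg))
  write_cohort(file.path(out, "cohort"), cohort)
  ann <- cohort$annotation
  train_ids <- ann$sample_id[ann$split == "train"]

  # 2. normalize + DE (training split only) --------------------------------
  rpm_all <- compute_rpm(cohort$mirna)
  rpm_train <- rpm_all[, train_ids, drop = FALSE]
  keep <- rownames(filter_low_expression(rpm_train, config$de$min_rpm,
                                         config$de$min_fraction))
  rpm_train <- rpm_train[keep, , drop = FALSE]
  rpm_all <- rpm_all[keep, , drop = FALSE]
  de <- timed("de", differential_expression(
    rpm_train, ann, alpha = config$de$alpha, test = config$de$test))
  .write_tsv(de, file.path(out, "de_results.tsv"))

  # 3. differential co-expression -----------------------------------------
  dcn_seed <- stage_seed(config$seed, "dcn")
  log_line("stage dcn        seed %d", dcn_seed)
  shifts <- timed("dcn", permutation_significance(
    rpm_train, ann, n_perm = config$dcn$n_perm, alpha = config$dcn$alpha,
    seed = dcn_seed))
  .write_tsv(shifts, file.path(out, "connectivity_shifts.tsv"))
  for (cond in c("positive", "negative")) {
    net <- build_network(rpm_train, ann, cond, tau = config$dcn$tau,
                         edge_alpha = config$dcn$edge_alpha)
    .write_tsv(net$edges, file.path(out, paste0("network_", cond, ".tsv")))
  }

  # 4. signature ------------------------------------------------------------
  sig <- suppressWarnings(intersect_signature(de, shifts, "recurrence"))
  jsonlite::write_json(
    list(context = sig$context, feature_ids = sig$feature_ids,
         provenance = sig$provenance),
    file.path(out, "signature.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  signature_report(sig, file.path(out, "signature_report.tsv"))

  summary <- list(
    seed = config$seed,
    n_features_tested = nrow(de),
    de = list(n_flagged = sum(de$significant),
              flagged_ids = sort(de$feature_id[de$significant])),
    dcn = list(n_altered = sum(shifts$altered),
               altered_ids = sort(shifts$feature_id[shifts$altered])),
    signature = list(size = length(sig$feature_ids),
                     feature_ids = sig$feature_ids))

  # 5. mRNA integration ------------------------------------------------------
  if (!is.null(cohort$mrna) && length(sig$feature_ids) > 0) {
    pairs <- timed("integrate", negative_correlation_pairs(
      rpm_all[, train_ids, drop = FALSE],
      cohort$mrna[, train_ids, drop = FALSE], sig,
      rho_threshold = config$integration$rho_threshold))
    .write_tsv(pairs, file.path(out, "correlation_pairs.tsv"))
    top <- top_anticorrelated(pairs, config$integration$top_k)
    .write_tsv(top, file.path(out, "top_targets.tsv"))
    summary$integration <- list(n_kept_pairs = sum(pairs$kept),
                                top_genes = top$gene_id)
  }

  # 6. multi-objective ensemble ---------------------------------------------
  fronts <- list()
  if (length(sig$feature_ids) == 0) {
    summary$note <- "no signature; classifier stage skipped"
  } else {
    moo_seed <- stage_seed(config$seed, "moo")
    log_line("stage moo        seed %d", moo_seed)
    scfg <- moo_search_config(population = config$moo$population,
                              generations = config$moo$generations,
                              folds = config$moo$folds)
    variants <- c("signature")
    if (config$moo$clinical != "none")
      variants <- c(variants, "signature_clinical")
    evaluation <- list()
    for (v in variants) {
      clin <- if (v == "signature") "none" else config$moo$clinical
      ft <- build_feature_table(rpm_all, sig, ann, clinical = clin)
      front <- timed(paste0("moo_", v), evolve(ft, scfg, seed = moo_seed))
      fronts[[v]] <- front
      cv <- cross_validate_ensemble(front, ft, k = config$moo$folds,
                                    seed = moo_seed)
      ens <- fit_ensemble(front, ft, seed = moo_seed)
      test <- ft$split == "test"
      test_rep <- NULL
      if (any(test)) {
        pred <- ensemble_predict(ens, ft$x[test, , drop = FALSE])
        test_rep <- evaluate_predictions(ft$y[test], pred)
      }
      evaluation[[v]] <- list(
        front_size = length(front$solutions),
        cross_validation = .report_as_list(cv),
        external_test = if (!is.null(test_rep)) .report_as_list(test_rep))
      obj <- .objective_matrix(front$solutions)
      front_tab <- data.frame(
        variant = v,
        classifier = vapply(front$solutions, `[[`, character(1),
                            "classifier"),
        features = vapply(front$solutions, function(s)
          paste(colnames(ft$x)[s$mask], collapse = ","), character(1)),
        cost = vapply(front$solutions, `[[`, numeric(1), "cost"),
        gamma = vapply(front$solutions, `[[`, numeric(1), "gamma"),
        n_trees = vapply(front$solutions, `[[`, numeric(1), "n_trees"),
        cv_accuracy = obj[, 1], n_selected = obj[, 2],
        complexity = obj[, 3], stringsAsFactors = FALSE)
      .write_tsv(front_tab, file.path(out, paste0("front_", v, ".tsv")))
    }
    summary$evaluation <- evaluation
  }

  # 7. truth comparison ------------------------------------------------------
  if (!is.null(cohort$truth))
    summary$recovery <- compare_to_truth(summary, cohort$truth)

  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line("pipeline complete")
  invisible(list(summary = summary, cohort = cohort, signature = sig,
                 fronts = fronts, output_dir = out))
}

#' Compare recovered sets against the planted ground truth
#'
#' Precision, recall and F1 of the recovered signature against the planted
#' one, plus per-stage recall: the fraction of planted DE miRNAs flagged by
#' the DE stage and of planted module miRNAs flagged by the
#' connectivity-shift stage (when the summary carries those id lists).
#'
#' @param summary A [run_pipeline()] summary list, or a character vector of
#'   recovered signature ids.
#' @param truth The cohort's ground-truth record.
#' @return List with `precision`, `recall`, `f1` and, when available,
#'   `de_stage_recall` and `dc_stage_recall`.
#' @export
compare_to_truth <- function(summary, truth) {
  recovered <- if (is.character(summary)) summary
               else summary$signature$feature_ids
  planted <- truth$signature_ids
  tp <- length(intersect(recovered, planted))
  precision <- if (length(recovered) > 0) tp / length(recovered) else 0
  recall <- if (length(planted) > 0) tp / length(planted) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  res <- list(precision = precision, recall = recall, f1 = f1)
  if (!is.character(summary)) {
    if (!is.null(summary$de) && nrow(truth$de_ids) > 0)
      res$de_stage_recall <- mean(truth$de_ids$feature_id %in%
                                    summary$de$flagged_ids)
    if (!is.null(summary$dcn) && length(truth$dc_ids) > 0)
      res$dc_stage_recall <- mean(truth$dc_ids %in%
                                    summary$dcn$altered_ids)
  }
  res
}
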