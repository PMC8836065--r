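#' Pareto dominance for (accuracy, n_selected, complexity) triples
#'
#' `a` dominates `b` when it is at least as good in every objective
#' (accuracy maximized; selected-feature count and model complexity
#' minimized) and strictly better in at least one.
#'
#' @param a,b Numeric triples `c(cv_accuracy, n_selected, complexity)`.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  ge <- a[1] >= b[1] && a[2] <= b[2] && a[3] <= b[3]
  strict <- a[1] > b[1] || a[2] < b[2] || a[3] < b[3]
  ge && strict
}

.objective_matrix <- function(solutions) {
  t(vapply(solutions, function(s) as.numeric(s$objectives), numeric(3)))
}

.candidate_key <- function(cand) {
  paste(cand$classifier, cand$cost, cand$gamma, cand$n_trees,
        paste(which(cand$mask), collapse = ","), sep = "|")
}

#' Extract the Pareto front of a set of candidate solutions
#'
#' Returns exactly the non-dominated subset under [dominates()], with
#' duplicates by (mask, classifier, hyperparameters) removed.
#'
#' @param solutions Non-empty list of candidate solutions, each a list with
#'   at least `objectives` (and `mask`, `classifier`, `cost`, `gamma`,
#'   `n_trees` for deduplication).
#' @return Object of class `pareto_front` (list with `solutions`).
#' @export
pareto_front <- function(solutions) {
  if (length(solutions) == 0) stop("no solutions supplied")
  keys <- vapply(solutions, .candidate_key, character(1))
  solutions <- solutions[!duplicated(keys)]
  obj <- .objective_matrix(solutions)
  n <- nrow(obj)
  nd <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j)
      j != i && dominates(obj[j, ], obj[i, ]), logical(1)))
  }, logical(1))
  structure(list(solutions = solutions[nd]), class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  obj <- .objective_matrix(x$solutions)
  cat("Pareto front with", length(x$solutions), "solution(s)\n")
  for (i in seq_along(x$solutions)) {
    s <- x$solutions[[i]]
    cat(sprintf("  [%d] %s acc=%.3f features=%d complexity=%.3f\n", i,
                s$classifier, obj[i, 1], obj[i, 2], obj[i, 3]))
  }
  invisible(x)
}

.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.fit_member <- function(classifier, x, y, cost, gamma, n_trees, fit_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(fit_seed)
  if (classifier == "svm_rbf") {
    e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE)
  } else {
    randomForest::randomForest(x, y, ntree = n_trees)
  }
}

#' Construct a candidate solution
#'
#' A point in the joint search space: a feature mask, a classifier family
#' and its hyperparameters. Hyperparameters of the other family are carried
#' but inert.
#'
#' @param mask Logical vector over the feature-table columns; at least one
#'   `TRUE`.
#' @param classifier `"svm_rbf"` or `"random_forest"`.
#' @param cost,gamma SVM cost and RBF width.
#' @param n_trees Random-forest size.
#' @return List of class `moo_candidate` (objectives unset).
#' @export
candidate_solution <- function(mask, classifier = c("svm_rbf",
                                                    "random_forest"),
                               cost = 1, gamma = 0.1, n_trees = 100) {
  classifier <- match.arg(classifier)
  structure(list(mask = as.logical(mask), classifier = classifier,
                 cost = cost, gamma = gamma, n_trees = n_trees,
                 objectives = NULL),
            class = "moo_candidate")
}

#' Evaluate a candidate by stratified k-fold cross-validation
#'
#' Objectives: `cv_accuracy` (mean held-out accuracy over `k` stratified
#' folds, one fixed fold assignment per `seed` shared by every candidate of
#' a run), `n_selected` (number of masked-in features) and `complexity`
#' (`n_trees / max_trees` for forests; mean support-vector fraction over
#' folds for SVMs — both in `[0, 1]`). An all-false mask is assigned the
#' worst objectives (accuracy 0, all features, complexity 1) so heuristic
#' search stays total. Deterministic given the seed.
#'
#' @param cand A [candidate_solution()].
#' @param table A [build_feature_table()] result; only training-split rows
#'   are used.
#' @param k Number of folds (default 5).
#' @param seed Integer run seed for fold assignment and classifier RNG.
#' @param max_trees Normalizer for forest complexity (default 500, the top
#'   of the default grid).
#' @return The candidate with `objectives` populated.
#' @export
evaluate_candidate <- function(cand, table, k = 5, seed = 1L,
                               max_trees = 500) {
  train <- table$split == "train"
  x <- table$x[train, , drop = FALSE]
  y <- droplevels(table$y[train])
  if (!any(cand$mask)) {
    cand$objectives <- c(cv_accuracy = 0, n_selected = ncol(table$x),
                         complexity = 1)
    return(cand)
  }
  xm <- x[, cand$mask, drop = FALSE]
  folds <- .stratified_folds(y, k, seed)
  acc <- cplx <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit_seed <- as.integer((as.numeric(seed) * 131 + f * 7 +
                              sum(which(cand$mask))) %% 2147483647)
    m <- .fit_member(cand$classifier, xm[tr, , drop = FALSE], y[tr],
                     cand$cost, cand$gamma, cand$n_trees, fit_seed)
    pred <- stats::predict(m, xm[!tr, , drop = FALSE])
    acc[f] <- mean(pred == y[!tr])
    cplx[f] <- if (cand$classifier == "svm_rbf") m$tot.nSV / sum(tr)
               else cand$n_trees / max_trees
  }
  cand$objectives <- c(cv_accuracy = mean(acc), n_selected = sum(cand$mask),
                       complexity = mean(cplx))
  cand
}

#' Search-space configuration for [evolve()]
#'
#' Defaults follow common practice for SVM grids (`C = 2^-5..2^15`,
#' `gamma = 2^-15..2^3`, steps of 2 on the exponent) and modest forest
#' sizes.
#'
#' @param population,generations NSGA-II population size (>= 4) and number
#'   of generations (>= 0).
#' @param folds Cross-validation folds for candidate evaluation.
#' @param classifiers Families available to the search.
#' @param c_grid,gamma_grid,trees_grid Hyperparameter grids.
#' @param p_crossover Probability a selected pair undergoes uniform
#'   crossover.
#' @param p_mut_clf,p_mut_hyper Per-gene mutation rates for the classifier
#'   flip and the +-1 hyperparameter grid step (mask bits mutate at rate
#'   `1 / n_features`).
#' @return List of class `moo_search_config`.
#' @export
moo_search_config <- function(population = 60, generations = 40, folds = 5,
                              classifiers = c("svm_rbf", "random_forest"),
                              c_grid = 2^seq(-5, 15, by = 2),
                              gamma_grid = 2^seq(-15, 3, by = 2),
                              trees_grid = c(50, 100, 200, 300, 500),
                              p_crossover = 0.9, p_mut_clf = 0.1,
                              p_mut_hyper = 0.2) {
  if (population < 4) stop("population must be at least 4")
  if (generations < 0) stop("generations must be >= 0")
  if (folds < 2) stop("folds must be >= 2")
  if (length(c_grid) < 1 || length(gamma_grid) < 1 || length(trees_grid) < 1)
    stop("hyperparameter grids must be non-empty")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 folds = as.integer(folds), classifiers = classifiers,
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 trees_grid = trees_grid, p_crossover = p_crossover,
                 p_mut_clf = p_mut_clf, p_mut_hyper = p_mut_hyper),
            class = "moo_search_config")
}

# fast non-dominated sorting: returns integer rank per row (1 = front)
.nds_rank <- function(obj) {
  n <- nrow(obj)
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(obj[i, ], obj[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(obj[j, ], obj[i, ])) {
        dom_count[i] <- dom_count[i] + 1L
      }
    }
  }
  rank <- integer(n)
  current <- which(dom_count == 0L)
  r <- 1L
  while (length(current) > 0) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      for (j in dominated_by[[i]]) {
        dom_count[j] <- dom_count[j] - 1L
        if (dom_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- unique(nxt)
    r <- r + 1L
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (rng > 0 && n > 2)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / rng
  }
  d
}

.random_genome <- function(nf, cfg) {
  mask <- stats::runif(nf) < 0.5
  if (!any(mask)) mask[sample(nf, 1)] <- TRUE
  list(mask = mask,
       clf = sample(length(cfg$classifiers), 1),
       ci = sample(length(cfg$c_grid), 1),
       gi = sample(length(cfg$gamma_grid), 1),
       ti = sample(length(cfg$trees_grid), 1))
}

.genome_to_candidate <- function(g, cfg) {
  candidate_solution(g$mask, cfg$classifiers[g$clf],
                     cost = cfg$c_grid[g$ci], gamma = cfg$gamma_grid[g$gi],
                     n_trees = cfg$trees_grid[g$ti])
}

.mutate_genome <- function(g, cfg) {
  nf <- length(g$mask)
  flip <- stats::runif(nf) < 1 / nf
  g$mask <- xor(g$mask, flip)
  if (!any(g$mask)) g$mask[sample(nf, 1)] <- TRUE
  if (length(cfg$classifiers) > 1 && stats::runif(1) < cfg$p_mut_clf)
    g$clf <- sample(setdiff(seq_along(cfg$classifiers), g$clf), 1)
  step <- function(i, len) max(1L, min(len, i + sample(c(-1L, 1L), 1)))
  if (stats::runif(1) < cfg$p_mut_hyper) g$ci <- step(g$ci,
                                                      length(cfg$c_grid))
  if (stats::runif(1) < cfg$p_mut_hyper) g$gi <- step(g$gi,
                                                      length(cfg$gamma_grid))
  if (stats::runif(1) < cfg$p_mut_hyper) g$ti <- step(g$ti,
                                                      length(cfg$trees_grid))
  g
}

.crossover_genomes <- function(a, b) {
  nf <- length(a$mask)
  swap <- stats::runif(nf) < 0.5
  m1 <- ifelse(swap, b$mask, a$mask)
  m2 <- ifelse(swap, a$mask, b$mask)
  pick <- function(x, y) if (stats::runif(1) < 0.5) x else y
  c1 <- list(mask = m1, clf = pick(a$clf, b$clf), ci = pick(a$ci, b$ci),
             gi = pick(a$gi, b$gi), ti = pick(a$ti, b$ti))
  c2 <- list(mask = m2, clf = pick(a$clf, b$clf), ci = pick(a$ci, b$ci),
             gi = pick(a$gi, b$gi), ti = pick(a$ti, b$ti))
  if (!any(c1$mask)) c1$mask[sample(nf, 1)] <- TRUE
  if (!any(c2$mask)) c2$mask[sample(nf, 1)] <- TRUE
  list(c1, c2)
}

#' Multi-objective NSGA-II-style search over subsets, classifiers and
#' hyperparameters
#'
#' Elitist non-dominated-sorting genetic search (selection by rank and
#' crowding distance via binary tournament, uniform crossover, per-gene
#' mutation) over the joint space of feature masks, classifier family and
#' hyperparameter grid indices. Every evaluated candidate enters an
#' archive; the returned front is the non-dominated set of the archive, so
#' more generations can never lose attained solutions. `generations = 0`
#' returns the front of the random initial population. Candidate
#' evaluations are cached, and one fold assignment (from `seed`) is shared
#' by all candidates so objectives are comparable across the population.
#'
#' @param table A [build_feature_table()] result.
#' @param search_config A [moo_search_config()].
#' @param seed Integer seed; fixed seed gives an identical front.
#' @return A `pareto_front` whose solutions carry populated objectives.
#' @export
evolve <- function(table, search_config = moo_search_config(), seed = 1L) {
  cfg <- search_config
  stopifnot(inherits(cfg, "moo_search_config"))
  nf <- ncol(table$x)
  max_trees <- max(cfg$trees_grid)
  cache <- new.env(parent = emptyenv())
  eval_genome <- function(g) {
    cand <- .genome_to_candidate(g, cfg)
    key <- .candidate_key(cand)
    if (exists(key, envir = cache, inherits = FALSE))
      return(get(key, envir = cache))
    cand <- evaluate_candidate(cand, table, k = cfg$folds, seed = seed,
                               max_trees = max_trees)
    cache[[key]] <- cand
    cand
  }
  set.seed(seed)
  pop <- replicate(cfg$population, .random_genome(nf, cfg),
                   simplify = FALSE)
  pop_cand <- lapply(pop, eval_genome)
  for (gen in seq_len(cfg$generations)) {
    obj <- .objective_matrix(pop_cand)
    key <- cbind(-obj[, 1], obj[, 2], obj[, 3])  # all minimized
    rank <- .nds_rank(key)
    crowd <- numeric(length(rank))
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- if (length(idx) > 2) .crowding(key[idx, , drop = FALSE])
                    else Inf
    }
    tournament <- function() {
      ij <- sample(length(pop), 2)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] >= crowd[j]) i else j
    }
    offspring <- list()
    while (length(offspring) < cfg$population) {
      pa <- pop[[tournament()]]
      pb <- pop[[tournament()]]
      kids <- if (stats::runif(1) < cfg$p_crossover)
        .crossover_genomes(pa, pb) else list(pa, pb)
      kids <- lapply(kids, .mutate_genome, cfg = cfg)
      offspring <- c(offspring, kids)
    }
    offspring <- offspring[seq_len(cfg$population)]
    off_cand <- lapply(offspring, eval_genome)
    # elitist environmental selection on parents + offspring
    all_pop <- c(pop, offspring)
    all_cand <- c(pop_cand, off_cand)
    obj <- .objective_matrix(all_cand)
    key <- cbind(-obj[, 1], obj[, 2], obj[, 3])
    rank <- .nds_rank(key)
    sel <- integer(0)
    for (r in sort(unique(rank))) {
      idx <- which(rank == r)
      if (length(sel) + length(idx) <= cfg$population) {
        sel <- c(sel, idx)
      } else {
        cr <- if (length(idx) > 2) .crowding(key[idx, , drop = FALSE])
              else rep(Inf, length(idx))
        sel <- c(sel, idx[order(cr, decreasing = TRUE)[
          seq_len(cfg$population - length(sel))]])
        break
      }
    }
    pop <- all_pop[sel]
    pop_cand <- all_cand[sel]
  }
  pareto_front(unname(as.list(mget(ls(cache), envir = cache))))
}

#' Fit the Pareto-front ensemble on the full training split
#'
#' Refits every front member on all training samples with its own mask and
#' hyperparameters; prediction is by unweighted majority vote with ties
#' going to the positive class (screening favors sensitivity).
#'
#' @param front A `pareto_front` from [evolve()] or [pareto_front()].
#' @param table The [build_feature_table()] the front was searched on.
#' @param seed Integer seed for classifier RNG.
#' @return Object of class `mirna_ensemble`.
#' @export
fit_ensemble <- function(front, table, seed = 1L) {
  stopifnot(inherits(front, "pareto_front"), length(front$solutions) >= 1)
  train <- table$split == "train"
  x <- table$x[train, , drop = FALSE]
  y <- droplevels(table$y[train])
  members <- lapply(seq_along(front$solutions), function(i) {
    s <- front$solutions[[i]]
    fit_seed <- as.integer((as.numeric(seed) * 131 + i) %% 2147483647)
    model <- .fit_member(s$classifier, x[, s$mask, drop = FALSE], y,
                         s$cost, s$gamma, s$n_trees, fit_seed)
    list(model = model, mask = s$mask, classifier = s$classifier)
  })
  structure(list(members = members, feature_names = colnames(table$x),
                 scaler = table$scaler),
            class = "mirna_ensemble")
}

.majority_vote <- function(votes) {
  # votes: samples x members matrix of "positive"/"negative"; ties -> positive
  npos <- rowSums(votes == "positive")
  factor(ifelse(npos * 2 >= ncol(votes), "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Predict labels with a fitted ensemble
#'
#' @param model A [fit_ensemble()] result.
#' @param newdata A `feature_table` (all rows predicted) or a numeric
#'   matrix already on the ensemble's scaled feature space.
#' @return Factor of predicted labels (`negative` / `positive`).
#' @export
ensemble_predict <- function(model, newdata) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else newdata
  if (!identical(colnames(x), model$feature_names))
    stop("feature mismatch between model (",
         paste(model$feature_names, collapse = ", "), ") and data (",
         paste(colnames(x), collapse = ", "), ")")
  votes <- vapply(model$members, function(m)
    as.character(stats::predict(m$model, x[, m$mask, drop = FALSE])),
    character(nrow(x)))
  if (nrow(x) == 1) votes <- matrix(votes, nrow = 1)
  .majority_vote(votes)
}

#' Accuracy, specificity and sensitivity of predictions
#'
#' `SEN = TP / (TP + FN) * 100`, `SP = TN / (TN + FP) * 100`,
#' `ACC = (TP + TN) / N * 100`. If a class is absent from the truth the
#' corresponding rate is `NA` and flagged `undefined`; accuracy is still
#' computed.
#'
#' @param y_true,y_pred Equal-length binary label vectors.
#' @param positive_label The label counted as positive (default
#'   `"positive"`).
#' @return List of class `evaluation_report` with `acc`, `sp`, `sen` (in
#'   percent), the confusion counts and an `undefined` character vector.
#' @export
evaluate_predictions <- function(y_true, y_pred,
                                 positive_label = "positive") {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  yt <- as.character(y_true) == positive_label
  yp <- as.character(y_pred) == positive_label
  tp <- sum(yt & yp); fn <- sum(yt & !yp)
  tn <- sum(!yt & !yp); fp <- sum(!yt & yp)
  undefined <- character(0)
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "sen"); NA_real_ }
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    undefined <- c(undefined, "sp"); NA_real_ }
  structure(list(acc = 100 * (tp + tn) / length(yt), sp = sp, sen = sen,
                 tp = tp, fn = fn, tn = tn, fp = fp,
                 undefined = undefined),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  SP %s  SEN %s\n", x$acc,
              ifelse(is.na(x$sp), "NA", sprintf("%.2f%%", x$sp)),
              ifelse(is.na(x$sen), "NA", sprintf("%.2f%%", x$sen))))
  invisible(x)
}

#' Cross-validated performance of the front ensemble
#'
#' Refits every front member inside each of `k` stratified folds of the
#' training split, votes on the held-out fold, and pools the held-out
#' predictions into one confusion matrix.
#'
#' @inheritParams fit_ensemble
#' @param k Number of folds.
#' @return An `evaluation_report`.
#' @export
cross_validate_ensemble <- function(front, table, k = 5, seed = 1L) {
  stopifnot(inherits(front, "pareto_front"), length(front$solutions) >= 1)
  train <- table$split == "train"
  x <- table$x[train, , drop = FALSE]
  y <- droplevels(table$y[train])
  folds <- .stratified_folds(y, k, seed)
  pred <- factor(rep("negative", length(y)),
                 levels = c("negative", "positive"))
  for (f in seq_len(k)) {
    tr <- folds != f
    votes <- vapply(seq_along(front$solutions), function(i) {
      s <- front$solutions[[i]]
      fit_seed <- as.integer((as.numeric(seed) * 131 + i * 17 + f) %%
                               2147483647)
      m <- .fit_member(s$classifier, x[tr, s$mask, drop = FALSE], y[tr],
                       s$cost, s$gamma, s$n_trees, fit_seed)
      as.character(stats::predict(m, x[!tr, s$mask, drop = FALSE]))
    }, character(sum(!tr)))
    if (sum(!tr) == 1) votes <- matrix(votes, nrow = 1)
    pred[!tr] <- .majority_vote(votes)
  }
  evaluate_predictions(y, pred)
}
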