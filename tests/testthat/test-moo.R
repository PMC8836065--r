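test_that("dominates implements strict Pareto dominance", {
  expect_true(dominates(c(0.90, 3, 0.2), c(0.90, 5, 0.3)))
  expect_false(dominates(c(0.90, 3, 0.2), c(0.90, 3, 0.2)))   # no strict
  expect_false(dominates(c(0.95, 6, 0.5), c(0.90, 2, 0.1)))   # incomparable
  expect_false(dominates(c(0.90, 2, 0.1), c(0.95, 6, 0.5)))
})

test_that("pareto_front equals brute-force filtering and deduplicates", {
  set.seed(10)
  obj <- cbind(runif(100), sample(1:10, 100, TRUE),
               runif(100))
  front <- pareto_front(wrap_objectives(obj))
  got <- sort(vapply(front$solutions, `[[`, numeric(1), "cost"))
  expect_equal(got, which(brute_force_front(obj)))

  sols <- wrap_objectives(obj[1:3, ])
  sols[[4]] <- sols[[1]]                 # exact duplicate solution
  n_unique <- length(pareto_front(sols)$solutions)
  expect_equal(n_unique, length(pareto_front(sols[1:3])$solutions))

  single <- wrap_objectives(obj[1, , drop = FALSE])
  expect_equal(length(pareto_front(single)$solutions), 1)
  expect_error(pareto_front(list()), "no solutions")
})

test_that("evaluate_candidate is deterministic and saturates on separable data", {
  tab <- make_separable_table()
  cand <- candidate_solution(rep(TRUE, 4), "svm_rbf", cost = 1,
                             gamma = 0.25)
  a <- evaluate_candidate(cand, tab, seed = 5)
  b <- evaluate_candidate(cand, tab, seed = 5)
  expect_identical(a$objectives, b$objectives)
  expect_equal(unname(a$objectives["cv_accuracy"]), 1)
  expect_equal(unname(a$objectives["n_selected"]), 4)
  expect_true(a$objectives["complexity"] >= 0 &&
                a$objectives["complexity"] <= 1)

  rf <- evaluate_candidate(candidate_solution(c(TRUE, TRUE, FALSE, FALSE),
                                              "random_forest",
                                              n_trees = 100),
                           tab, seed = 5)
  expect_equal(unname(rf$objectives["cv_accuracy"]), 1)
  expect_equal(unname(rf$objectives["complexity"]), 100 / 500)

  worst <- evaluate_candidate(candidate_solution(rep(FALSE, 4)), tab)
  expect_equal(unname(worst$objectives),
               c(0, 4, 1))               # worst objectives keep search total
})

test_that("evolve on a tiny restricted space matches exhaustive enumeration", {
  tab <- make_separable_table(n_per_class = 20, n_features = 3, gap = 2,
                              seed = 2)
  cfg <- moo_search_config(population = 12, generations = 10,
                           classifiers = "svm_rbf", c_grid = 1,
                           gamma_grid = 1 / 3, trees_grid = 100)
  front <- evolve(tab, cfg, seed = 8)
  # exhaustive oracle over all 7 non-empty masks
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), 3))[-1, ]
  all_cands <- lapply(seq_len(nrow(masks)), function(i)
    evaluate_candidate(candidate_solution(unlist(masks[i, ]), "svm_rbf",
                                          cost = 1, gamma = 1 / 3),
                       tab, k = cfg$folds, seed = 8))
  obj <- t(vapply(all_cands, function(s) unname(s$objectives), numeric(3)))
  oracle_keys <- sort(vapply(all_cands[brute_force_front(obj)],
                             mirpareto:::.candidate_key, character(1)))
  got_keys <- sort(unname(vapply(front$solutions,
                                 mirpareto:::.candidate_key,
                                 character(1))))
  expect_equal(got_keys, oracle_keys)

  front2 <- evolve(tab, cfg, seed = 8)   # same seed, identical front
  expect_equal(vapply(front2$solutions, mirpareto:::.candidate_key,
                      character(1)),
               vapply(front$solutions, mirpareto:::.candidate_key,
                      character(1)))
})

test_that("longer runs never lose attained front solutions (elitist archive)", {
  tab <- make_separable_table(n_per_class = 15, n_features = 5, gap = 1.2,
                              seed = 3)
  cfg1 <- moo_search_config(population = 8, generations = 2,
                            classifiers = "svm_rbf",
                            c_grid = c(0.1, 1, 10), gamma_grid = 0.2,
                            trees_grid = 100)
  cfg2 <- cfg1
  cfg2$generations <- 6L
  f1 <- evolve(tab, cfg1, seed = 4)
  f2 <- evolve(tab, cfg2, seed = 4)
  o1 <- t(vapply(f1$solutions, function(s) unname(s$objectives), numeric(3)))
  o2 <- t(vapply(f2$solutions, function(s) unname(s$objectives), numeric(3)))
  # every G1 front member is weakly dominated by some G2 front member,
  # hence the G2 front's hypervolume cannot be smaller
  for (i in seq_len(nrow(o1))) {
    covered <- any(vapply(seq_len(nrow(o2)), function(j)
      o2[j, 1] >= o1[i, 1] && o2[j, 2] <= o1[i, 2] &&
        o2[j, 3] <= o1[i, 3], logical(1)))
    expect_true(covered)
  }
})

test_that("generations = 0 returns the front of the initial population", {
  tab <- make_separable_table(n_per_class = 10, n_features = 3, gap = 3,
                              seed = 6)
  cfg <- moo_search_config(population = 6, generations = 0,
                           classifiers = "svm_rbf", c_grid = 1,
                           gamma_grid = 0.3, trees_grid = 100)
  front <- evolve(tab, cfg, seed = 9)
  expect_gte(length(front$solutions), 1)
  expect_lte(length(front$solutions), 6)
})

test_that("ensemble voting follows majority with ties to positive", {
  votes <- matrix(c("positive", "negative", "positive",
                    "negative", "negative", "positive"),
                  nrow = 2, byrow = TRUE)
  expect_equal(as.character(mirpareto:::.majority_vote(votes)),
               c("positive", "negative"))
  tie <- matrix(c("positive", "negative"), nrow = 1)
  expect_equal(as.character(mirpareto:::.majority_vote(tie)), "positive")

  tab <- make_separable_table(seed = 7)
  cand <- evaluate_candidate(candidate_solution(rep(TRUE, 4), "svm_rbf",
                                                cost = 1, gamma = 0.25),
                             tab, seed = 2)
  single <- pareto_front(list(cand))
  ens <- fit_ensemble(single, tab, seed = 2)
  pred_ens <- ensemble_predict(ens, tab)
  pred_member <- predict(ens$members[[1]]$model,
                         tab$x[, ens$members[[1]]$mask, drop = FALSE])
  expect_equal(as.character(pred_ens), as.character(pred_member))

  # unanimous members return the common label whatever the front size
  uni <- matrix("negative", nrow = 3, ncol = 5)
  expect_equal(as.character(mirpareto:::.majority_vote(uni)),
               rep("negative", 3))

  expect_error(ensemble_predict(ens, tab$x[, 1:2]), "feature mismatch")
})

test_that("evaluate_predictions computes the confusion-matrix rates", {
  perfect <- evaluate_predictions(rep(c("positive", "negative"), 5),
                                  rep(c("positive", "negative"), 5))
  expect_equal(c(perfect$acc, perfect$sp, perfect$sen), c(100, 100, 100))

  y_true <- c(rep("positive", 10), rep("negative", 10))
  y_pred <- c(rep("positive", 8), rep("negative", 2),
              rep("negative", 7), rep("positive", 3))
  r <- evaluate_predictions(y_true, y_pred)
  expect_equal(c(r$sen, r$sp, r$acc), c(80, 70, 75))

  allpos <- evaluate_predictions(y_true, rep("positive", 20))
  expect_equal(c(allpos$sen, allpos$sp, allpos$acc), c(100, 0, 50))

  onecls <- evaluate_predictions(rep("positive", 4),
                                 c("positive", "positive", "negative",
                                   "positive"))
  expect_true(is.na(onecls$sp))
  expect_equal(onecls$undefined, "sp")
  expect_equal(onecls$acc, 75)
})
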