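# Shared fixtures, all generated in code.

# small annotation for a hand-built count matrix
make_annotation <- function(sample_ids, labels,
                            split = rep("train", length(sample_ids))) {
  data.frame(sample_id = sample_ids, label = labels,
             sample_type = rep("metastatic", length(sample_ids)),
             ajcc_t = rep("T2", length(sample_ids)),
             ajcc_stage = rep("II", length(sample_ids)),
             split = split, stringsAsFactors = FALSE)
}

# rpm-scale matrix with named rows/columns from a plain matrix
as_expr <- function(values, feature_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- feature_ids %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- sample_ids %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# linearly separable two-class feature table, all training split
make_separable_table <- function(n_per_class = 30, n_features = 4,
                                 gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * n_features), n_per_class),
             matrix(rnorm(n_per_class * n_features, mean = gap),
                    n_per_class))
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  y <- factor(rep(c("negative", "positive"), each = n_per_class),
              levels = c("negative", "positive"))
  structure(list(x = scale(x), y = y,
                 split = rep("train", nrow(x)),
                 sample_ids = sprintf("s%03d", seq_len(nrow(x))),
                 scaler = list(center = attr(scale(x), "scaled:center"),
                               scale = attr(scale(x), "scaled:scale"))),
            class = "feature_table")
}

# brute-force O(n^2) Pareto filter, independent of the package's code path
brute_force_front <- function(obj) {
  n <- nrow(obj)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      if (i == j) return(FALSE)
      ge <- obj[j, 1] >= obj[i, 1] && obj[j, 2] <= obj[i, 2] &&
        obj[j, 3] <= obj[i, 3]
      st <- obj[j, 1] > obj[i, 1] || obj[j, 2] < obj[i, 2] ||
        obj[j, 3] < obj[i, 3]
      ge && st
    }, logical(1)))
  }, logical(1))
}

# wrap objective triples as minimal candidate solutions for pareto_front()
# (cost = i keeps every solution's key unique so none are deduplicated)
wrap_objectives <- function(obj) {
  lapply(seq_len(nrow(obj)), function(i)
    list(mask = TRUE, classifier = "svm_rbf", cost = i, gamma = 1,
         n_trees = 100, objectives = obj[i, ]))
}
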