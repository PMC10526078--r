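# Random forest: bagged gini-split CART trees with per-split feature
# subsampling and a minimum leaf size (the regularizer tuned in the
# per-pixel baselines).

rf_fit <- function(X, y, n_trees = 50, min_samples_leaf = 1000,
                   mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(length(unique(y)) == 2)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  min_leaf <- as.integer(min(min_samples_leaf, max(1, nrow(X) %/% 2)))
  fit <- .rf_fit_cpp(X, as.integer(y), as.integer(n_trees),
                     as.integer(mtry), min_leaf, as.integer(seed))
  structure(list(trees = fit$trees, max_depths = fit$max_depths,
                 n_trees = n_trees, min_samples_leaf = min_samples_leaf,
                 mtry = mtry),
            class = "palseg_rf")
}

rf_prob <- function(model, X) as.numeric(.rf_predict_cpp(model$trees,
                                                         as.matrix(X)))

rf_predict <- function(model, X) as.integer(rf_prob(model, X) > 0.5)
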