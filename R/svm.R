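# Soft-margin SVM with radial-basis-function kernel, solved with a
# simplified SMO on the precomputed kernel matrix. Training is capped at
# max_train points (stratified subsample) since the kernel matrix is dense.

svm_fit <- function(X, y, C = 16, gamma = NULL, seed = 1L,
                    max_train = 3000, tol = 1e-3, max_passes = 5) {
  X <- as.matrix(X)
  stopifnot(length(unique(y)) == 2)
  if (nrow(X) > max_train) {
    keep <- withr::with_seed(seed, {
      pos <- which(y == 1); neg <- which(y == 0)
      npos <- min(length(pos), max_train %/% 2)
      c(sample(pos, npos), sample(neg, min(length(neg), max_train - npos)))
    })
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  if (is.null(gamma)) {
    v <- mean(apply(X, 2, stats::var))
    gamma <- 1 / (ncol(X) * max(v, 1e-12))  # scikit-learn "scale" default
  }
  ysign <- ifelse(y == 1, 1, -1)
  K <- .rbf_kernel_cpp(X, X, gamma)
  sol <- .svm_smo_cpp(K, ysign, C, tol, as.integer(max_passes),
                      as.integer(seed))
  sv <- which(sol$alpha > 1e-8)
  structure(list(sv = X[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * ysign[sv], b = sol$b,
                 gamma = gamma, C = C, n_sv = length(sv)),
            class = "palseg_svm")
}

svm_decision <- function(model, X, chunk = 20000L) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  for (start in seq(1, nrow(X), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(X))
    K <- .rbf_kernel_cpp(X[idx, , drop = FALSE], model$sv, model$gamma)
    out[idx] <- as.numeric(K %*% model$coef) + model$b
  }
  out
}

svm_predict <- function(model, X) as.integer(svm_decision(model, X) > 0)
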