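# Quadratic discriminant analysis with a ridge fallback for degenerate
# class covariances. Used both as the per-pixel QDA baseline and as the
# wrapped classifier inside sequential wavelength selection.

qda_fit <- function(X, y, ridge = 0) {
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("QDA needs both classes present")
  fit_class <- function(k) {
    Xi <- X[y == k, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- stats::cov(Xi)
    if (nrow(Xi) < 2) S <- diag(1e-4, ncol(X))
    eps <- ridge
    repeat {
      Sr <- S + diag(eps * max(mean(diag(S)), 1e-12), ncol(S))
      ch <- tryCatch(chol(Sr), error = function(e) NULL)
      if (!is.null(ch) && all(diag(ch) > 1e-10)) {
        return(list(mu = mu, chol = ch,
                    logdet = 2 * sum(log(diag(ch))),
                    prior = nrow(Xi) / nrow(X), ridged = eps > ridge))
      }
      eps <- if (eps == 0) 1e-6 else eps * 10
      if (eps > 1) stop("QDA covariance irreparably singular")
    }
  }
  fits <- lapply(classes, fit_class)
  names(fits) <- as.character(classes)
  if (any(vapply(fits, `[[`, TRUE, "ridged"))) {
    message("qda_fit: singular class covariance, ridge regularization applied")
  }
  structure(list(classes = classes, fits = fits, p = ncol(X)),
            class = "palseg_qda")
}

# log-discriminant scores, one column per class
qda_scores <- function(model, X) {
  X <- as.matrix(X)
  sc <- matrix(0, nrow(X), length(model$classes))
  for (j in seq_along(model$classes)) {
    f <- model$fits[[j]]
    Z <- backsolve(f$chol, t(X) - f$mu, transpose = TRUE)
    sc[, j] <- -0.5 * colSums(Z^2) - 0.5 * f$logdet + log(f$prior)
  }
  sc
}

qda_predict <- function(model, X) {
  sc <- qda_scores(model, X)
  # ties resolve to the first (lower) class = non-ablated
  model$classes[max.col(sc, ties.method = "first")]
}
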