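# Single-hidden-layer neural network (ReLU hidden units, softmax output)
# trained with Adam on the full batch, early-stopped on held-out loss.

mlp_fit <- function(X, y, hidden = 53, seed = 1L, lr = 0.01,
                    epochs = 150, patience = 20, val_frac = 0.1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(unique(y)) == 2)
  Y <- cbind(1 - y, y)  # column 1 = non-ablated, column 2 = ablated

  withr::with_seed(seed, {
    val <- sample(n, max(1, round(val_frac * n)))
    W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- numeric(hidden)
    W2 <- matrix(stats::rnorm(hidden * 2, sd = sqrt(2 / hidden)), hidden, 2)
    b2 <- numeric(2)
  })
  tr <- setdiff(seq_len(n), val)
  Xt <- X[tr, , drop = FALSE]; Yt <- Y[tr, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]; Yv <- Y[val, , drop = FALSE]

  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  adam <- adam_init(params)
  forward <- function(par, X) {
    H <- pmax(sweep(X %*% par$W1, 2, par$b1, "+"), 0)
    S <- sweep(H %*% par$W2, 2, par$b2, "+")
    S <- S - apply(S, 1, max)
    P <- exp(S)
    P <- P / rowSums(P)
    list(H = H, P = P)
  }
  ce <- function(P, Y) -mean(log(rowSums(P * Y) + 1e-12))

  best <- list(loss = Inf, par = params, since = 0L)
  trace <- numeric(0)
  for (e in seq_len(epochs)) {
    fw <- forward(params, Xt)
    dS <- (fw$P - Yt) / nrow(Xt)
    g <- list(
      W1 = crossprod(Xt, (dS %*% t(params$W2)) * (fw$H > 0)),
      b1 = colSums((dS %*% t(params$W2)) * (fw$H > 0)),
      W2 = crossprod(fw$H, dS),
      b2 = colSums(dS))
    upd <- adam_step(adam, params, g, lr)
    params <- upd$params; adam <- upd$state
    vl <- ce(forward(params, Xv)$P, Yv)
    trace <- c(trace, vl)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, par = params, since = 0L)
    } else {
      best$since <- best$since + 1L
      if (best$since >= patience) break
    }
  }
  structure(list(params = best$par, hidden = hidden, val_loss = best$loss,
                 trace = trace),
            class = "palseg_mlp")
}

mlp_scores <- function(model, X) {
  par <- model$params
  H <- pmax(sweep(as.matrix(X) %*% par$W1, 2, par$b1, "+"), 0)
  sweep(H %*% par$W2, 2, par$b2, "+")
}

mlp_predict <- function(model, X) {
  sc <- mlp_scores(model, X)
  as.integer(sc[, 2] > sc[, 1])
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
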