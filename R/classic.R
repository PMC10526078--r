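#' Specify a per-pixel classifier
#'
#' The four per-pixel baseline families with their tuned defaults: QDA (no
#' tunables), a single-hidden-layer neural network (53 hidden nodes), an
#' RBF-kernel SVM (C = 16) and a random forest (50 trees, minimum 1000
#' samples per leaf).
#'
#' @param family One of `"qda"`, `"nn"`, `"svm"`, `"rf"`.
#' @param ... Family-specific overrides: `hidden_nodes` (nn); `C`,
#'   `max_train` (svm); `n_trees`, `min_samples_leaf` (rf).
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("qda", "nn", "svm", "rf"), ...) {
  family <- match.arg(family)
  hp <- switch(family,
    qda = list(),
    nn = list(hidden_nodes = 53, lr = 0.01, epochs = 150, patience = 20),
    svm = list(kernel = "rbf", C = 16, max_train = 3000),
    rf = list(n_trees = 50, min_samples_leaf = 1000))
  override <- list(...)
  bad <- setdiff(names(override), names(hp))
  if (length(bad)) stop("unknown hyperparameter(s) for ", family, ": ",
                        paste(bad, collapse = ", "))
  hp[names(override)] <- override
  structure(list(family = family, hyperparams = hp), class = "model_spec")
}

#' Train a per-pixel classifier
#'
#' @param spec A [model_spec()].
#' @param dataset A balanced [pixel_dataset] (see [balance_pixels()]); both
#'   classes must be present.
#' @param seed Seed controlling any training randomness.
#' @return A `classic_model` exposing per-spectrum prediction.
#' @export
train_classic <- function(spec, dataset, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(dataset, "pixel_dataset"))
  X <- dataset$features
  y <- dataset$labels
  if (length(unique(y)) < 2) stop("training set contains a single class")
  hp <- spec$hyperparams
  fit <- switch(spec$family,
    qda = qda_fit(X, y),
    nn = mlp_fit(X, y, hidden = hp$hidden_nodes, seed = seed, lr = hp$lr,
                 epochs = hp$epochs, patience = hp$patience),
    svm = svm_fit(X, y, C = hp$C, seed = seed, max_train = hp$max_train),
    rf = rf_fit(X, y, n_trees = hp$n_trees,
                min_samples_leaf = hp$min_samples_leaf, seed = seed))
  structure(list(spec = spec, fit = fit, grid = dataset$grid),
            class = "classic_model")
}

#' @export
print.classic_model <- function(x, ...) {
  cat(sprintf("<classic_model> %s on %d wavelengths\n",
              toupper(x$spec$family), length(x$grid$values)))
  invisible(x)
}

# decision scores (positive = ablated) for an n x Lambda spectra matrix
classic_scores <- function(model, X) {
  switch(model$spec$family,
    qda = { s <- qda_scores(model$fit, X); s[, 2] - s[, 1] },
    nn = { s <- mlp_scores(model$fit, X); s[, 2] - s[, 1] },
    svm = svm_decision(model$fit, X),
    rf = rf_prob(model$fit, X) - 0.5)
}

#' Predict ablation labels for a matrix of spectra
#'
#' @param model A [train_classic()] model.
#' @param X n x Lambda matrix of normalized spectra.
#' @return Integer vector, 1 = ablated, 0 = non-ablated (ties to
#'   non-ablated).
#' @export
predict_pixels <- function(model, X) {
  if (ncol(X) != length(model$grid$values)) {
    stop(sprintf("model expects %d wavelengths, got %d",
                 length(model$grid$values), ncol(X)))
  }
  as.integer(classic_scores(model, X) > 0)
}

#' Segment a frame with a per-pixel classifier
#'
#' Every pixel (labeled or not) is classified independently from its
#' normalized spectrum.
#'
#' @param model A [train_classic()] model.
#' @param frame A preprocessed [pa_frame()] whose wavelength grid matches
#'   the model.
#' @return A [segmentation_result()].
#' @export
segment_frame <- function(model, frame) {
  stopifnot(inherits(model, "classic_model"), inherits(frame, "pa_frame"))
  if (frame$cube$state != "max_normalized") {
    stop("frame must be preprocessed before segmentation")
  }
  if (!grids_equal(model$grid, frame$cube$grid)) {
    stop("frame wavelength grid does not match the trained model")
  }
  d <- dim(frame$cube$intensities)
  X <- matrix(frame$cube$intensities, d[1] * d[2], d[3])
  s <- classic_scores(model, X)
  scores <- array(0, dim = c(d[1], d[2], 2))
  scores[, , 1] <- matrix(-s, d[1], d[2])
  scores[, , 2] <- matrix(s, d[1], d[2])
  segmentation_result(scores, decision = matrix(as.integer(s > 0),
                                                d[1], d[2]))
}

#' Hyperparameter tuning curve
#'
#' Trains one model per candidate value on the pixels of the tuning-train
#' frames and reports the mean F1 score over the tuning-validation frames,
#' reproducing the curve-based hyperparameter selection workflow.
#'
#' @param family Model family (see [model_spec()]).
#' @param param_name Hyperparameter to sweep.
#' @param values Candidate values.
#' @param trainA,validB Disjoint-by-block lists of preprocessed
#'   [pa_frame()].
#' @param seed Seed for balancing and training.
#' @return `data.frame(value, f1)`, plus a `max_depth` column for random
#'   forests.
#' @export
tuning_curve <- function(family, param_name, values, trainA, validB,
                         seed = 1L) {
  blocksA <- unique(vapply(trainA, function(f) as.character(f$block_id), ""))
  blocksB <- unique(vapply(validB, function(f) as.character(f$block_id), ""))
  if (length(intersect(blocksA, blocksB))) {
    stop("tuning train and validation sets share block(s): ",
         paste(intersect(blocksA, blocksB), collapse = ", "))
  }
  dataset <- balance_pixels(extract_pixels(trainA), seed = seed)
  rows <- lapply(values, function(v) {
    spec <- do.call(model_spec, c(list(family = family),
                                  stats::setNames(list(v), param_name)))
    model <- train_classic(spec, dataset, seed = seed)
    f1 <- score_algorithm(lapply(validB, function(fr) {
      list(result = segment_frame(model, fr), mask = fr$mask)
    }))
    out <- data.frame(value = v, f1 = f1)
    if (family == "rf") out$max_depth <- max(model$fit$max_depths)
    out
  })
  do.call(rbind, rows)
}
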