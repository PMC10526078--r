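#' Architecture of the fully convolutional segmenter
#'
#' Six layers: three blocks of (3x3 zero-padded convolution to 53 channels,
#' ReLU, 2x2 max-pool stride 2), a 1x1 convolution 53 -> 53 with ReLU, a
#' 1x1 convolution 53 -> 2 with ReLU, and a bilinear upsampling layer back
#' to the input H x W. The per-pixel argmax of the two upsampled score
#' channels (ties to non-ablated) is the segmentation.
#'
#' @param in_channels Wavelength count of the input cube.
#' @param hidden Feature channels of every intermediate layer (53).
#' @return A `cnn_spec`.
#' @export
cnn_spec <- function(in_channels, hidden = 53) {
  stopifnot(in_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 hidden = as.integer(hidden), classes = 2L),
            class = "cnn_spec")
}

#' Pooled feature-map dimensions
#'
#' Spatial size after the three 2x2 stride-2 max-pools (floor semantics);
#' bilinear upsampling restores the exact input size afterwards.
#'
#' @param h,w Input spatial dimensions.
#' @return `c(h, w)` after three halvings.
#' @export
cnn_pooled_dims <- function(h, w) c(h %/% 2 %/% 2 %/% 2, w %/% 2 %/% 2 %/% 2)

#' Initialize CNN weights
#'
#' Fan-in-scaled (He) Gaussian initialization, deterministic given the seed.
#'
#' @param spec A [cnn_spec()].
#' @param seed Random seed.
#' @return A `cnn_model` (untrained).
#' @export
cnn_build <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  h <- spec$hidden
  init <- function(fan_in, fan_out) {
    matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
           fan_in, fan_out)
  }
  weights <- withr::with_seed(seed, list(
    W1 = init(9 * spec$in_channels, h), b1 = numeric(h),
    W2 = init(9 * h, h), b2 = numeric(h),
    W3 = init(9 * h, h), b3 = numeric(h),
    W4 = init(h, h), b4 = rep(0.1, h),
    # small positive score-head biases keep the ReLU'd output channels
    # alive at the start of training (a dead 2-channel score map has zero
    # gradient everywhere and cannot recover)
    W5 = init(h, spec$classes), b5 = rep(0.5, spec$classes)))
  structure(list(spec = spec, weights = weights, grid = NULL,
                 loss_trace = numeric(0)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$weights, length, 0))
  cat(sprintf("<cnn_model> %d input channels, %d parameters%s\n",
              x$spec$in_channels, np,
              if (length(x$loss_trace)) sprintf(", trained %d epochs",
                                                length(x$loss_trace))
              else " (untrained)"))
  invisible(x)
}

check_cnn_input <- function(model, arr) {
  d <- if (is.null(dim(arr))) arr else dim(arr)
  if (d[3] != model$spec$in_channels) {
    stop(sprintf("model expects %d channels, frame has %d",
                 model$spec$in_channels, d[3]))
  }
  if (d[1] < 8 || d[2] < 8) {
    stop("input smaller than 8 x 8 collapses under three 2x2 max-pools")
  }
  invisible(d)
}

#' Weighted cross-entropy segmentation loss
#'
#' Softmax cross-entropy over the two score channels, averaged with
#' per-pixel weights: 1 for non-ablated, `weights$w_ablated` for ablated,
#' 0 for unlabeled pixels (which therefore contribute neither loss nor
#' gradient). The normalizer is the sum of the weights.
#'
#' @param scores H x W x 2 score array.
#' @param mask A [label_mask()] of the same H x W.
#' @param weights A [class_weights()] object (or list with `w_ablated`).
#' @return Non-negative scalar; 0 for an all-unlabeled mask.
#' @export
cnn_loss <- function(scores, mask, weights) {
  stopifnot(length(dim(scores)) == 3, dim(scores)[3] == 2,
            all(dim(mask) == dim(scores)[1:2]))
  codes <- unclass(mask)
  w <- ifelse(codes == MASK_ABLATED, weights$w_ablated,
              ifelse(codes == MASK_NON_ABLATED, 1, 0))
  if (sum(w) == 0) return(0)
  s1 <- scores[, , 1]; s2 <- scores[, , 2]
  m <- pmax(s1, s2)
  lse <- m + log(exp(s1 - m) + exp(s2 - m))
  ce <- ifelse(codes == MASK_ABLATED, lse - s2, lse - s1)
  sum(w * ce) / sum(w)
}

#' Training configuration for the segmenter
#'
#' @param epochs Training epochs (200 at full scale; desk-scale runs use
#'   fewer).
#' @param lr Adam learning rate.
#' @param batch_size Frames per Adam step.
#' @param clip Global L2 gradient-norm cap per step; stabilizes the
#'   ReLU-score head against dead-unit collapse.
#' @param seed Seed for weight init and epoch shuffling.
#' @return A `cnn_train_config`.
#' @export
cnn_train_config <- function(epochs = 200, lr = 1e-3, batch_size = 4,
                             clip = 1, seed = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), clip = clip,
                 seed = as.integer(seed)),
            class = "cnn_train_config")
}

#' Train the segmenter
#'
#' Minimizes the class-weighted cross-entropy with Adam over mini-batches of
#' whole frames. The ablated-class weight is the global
#' non-ablated:ablated labeled-pixel ratio of the training frames.
#' Deterministic given the seed.
#'
#' @param model A [cnn_build()] model (its weights are the starting point).
#' @param frames Preprocessed training [pa_frame()] list sharing one
#'   wavelength grid.
#' @param config A [cnn_train_config()].
#' @return The trained `cnn_model` with `loss_trace` (mean loss per epoch)
#'   and the training grid attached.
#' @export
cnn_fit <- function(model, frames, config = cnn_train_config()) {
  stopifnot(inherits(model, "cnn_model"), length(frames) > 0)
  for (fr in frames) {
    if (fr$cube$state != "max_normalized") {
      stop("all training frames must be preprocessed")
    }
    check_cnn_input(model, dim(fr$cube$intensities))
  }
  nl <- vapply(frames, function(f) dim(f$cube$intensities)[3], 0)
  if (length(unique(nl)) != 1) stop("inconsistent channel counts in frames")
  w_abl <- class_weights(frames)$w_ablated

  n <- length(frames)
  order_seed <- config$seed + 104729L
  has_lesion <- vapply(frames,
                       function(f) any(unclass(f$mask) == MASK_ABLATED),
                       TRUE)

  lesion_probe <- which(has_lesion)[1]

  run_schedule <- function(weights, attempt) {
    adam <- adam_init(weights)
    trace <- numeric(config$epochs)
    dead <- FALSE
    for (e in seq_len(config$epochs)) {
      ord <- withr::with_seed((order_seed + e + 7717L * attempt) %%
                                .Machine$integer.max,
                              sample.int(n))
      epoch_loss <- 0
      epoch_gnorm <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, n)]
        acc <- NULL
        bl <- 0
        for (i in batch) {
          fr <- frames[[i]]
          res <- .cnn_loss_grad_cpp(fr$cube$intensities, unclass(fr$mask),
                                    w_abl, weights, TRUE)
          g <- lapply(res$grads, function(x) {
            if (is.matrix(x) && nrow(x) == 1) as.numeric(x) else x
          })
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
          bl <- bl + res$loss
        }
        acc <- lapply(acc, function(x) x / length(batch))
        gn <- sqrt(sum(vapply(acc, function(x) sum(x^2), 0)))
        epoch_gnorm <- epoch_gnorm + gn
        if (is.finite(config$clip) && gn > config$clip) {
          acc <- lapply(acc, function(x) x * (config$clip / gn))
        }
        upd <- adam_step(adam, weights, acc[names(weights)], config$lr)
        weights <- upd$params
        adam <- upd$state
        epoch_loss <- epoch_loss + bl
      }
      trace[e] <- epoch_loss / n
      if (epoch_gnorm == 0) {  # fully dead ReLU head: cannot recover
        dead <- TRUE
        break
      }
      # resuscitate a floored ablated channel: once its score hits the
      # ReLU floor on every lesion pixel it emits no gradient and stays
      # dead, so lift its bias back into the active region and continue
      if (!is.na(lesion_probe) && e < config$epochs) {
        sc <- .cnn_forward_cpp(frames[[lesion_probe]]$cube$intensities,
                               weights)
        if (!any(sc[, , 2] > 0)) {
          weights$b5[2] <- weights$b5[2] + 0.5
        }
      }
    }
    list(weights = weights, trace = trace, dead = dead)
  }

  # the ReLU'd two-channel score head can die (zero gradient everywhere)
  # or settle into a degenerate never-claims-a-lesion solution; after the
  # schedule the net must call at least one pixel ablated on some
  # lesion-bearing training frame, else it is retrained from a fresh
  # seeded initialization with a fresh batch order
  claims_lesions <- function(weights) {
    check <- which(has_lesion)
    if (length(check) == 0) return(TRUE)
    check <- check[seq_len(min(4, length(check)))]
    for (i in check) {
      sc <- .cnn_forward_cpp(frames[[i]]$cube$intensities, weights)
      if (any(sc[, , 2] > sc[, , 1])) return(TRUE)
    }
    FALSE
  }

  attempt <- 0L
  weights <- model$weights
  repeat {
    fit <- run_schedule(weights, attempt)
    if (!fit$dead && claims_lesions(fit$weights)) break
    if (attempt >= 3L) {
      warning("cnn_fit: score head stayed dead after 3 restarts")
      break
    }
    attempt <- attempt + 1L
    message("cnn_fit: dead score head, restarting (attempt ", attempt, ")")
    weights <- cnn_build(model$spec,
                         seed = (config$seed + 9973L * attempt) %%
                           .Machine$integer.max)$weights
  }
  model$weights <- fit$weights
  model$loss_trace <- fit$trace
  model$restarts <- attempt
  model$grid <- frames[[1]]$cube$grid
  model
}

#' Per-frame loss and gradients (internal training step, exposed for
#' inspection)
#'
#' @param model A `cnn_model`.
#' @param frame A preprocessed [pa_frame()].
#' @param w_ablated Ablated-class loss weight.
#' @return List with `loss`, `weight_sum` and `grads` (named like the weight
#'   list).
#' @export
cnn_gradients <- function(model, frame, w_ablated) {
  check_cnn_input(model, dim(frame$cube$intensities))
  res <- .cnn_loss_grad_cpp(frame$cube$intensities, unclass(frame$mask),
                            w_ablated, model$weights, TRUE)
  res$grads <- lapply(res$grads, function(x) {
    if (is.matrix(x) && nrow(x) == 1) as.numeric(x) else x
  })
  res
}

#' Segment a frame with the CNN
#'
#' @param model A trained `cnn_model`.
#' @param frame A preprocessed [pa_frame()]; its wavelength grid must match
#'   the grid the model was trained on.
#' @return A [segmentation_result()]; the decision is the per-pixel argmax
#'   of the two score channels with ties resolved to non-ablated.
#' @export
cnn_segment <- function(model, frame) {
  stopifnot(inherits(model, "cnn_model"), inherits(frame, "pa_frame"))
  if (frame$cube$state != "max_normalized") {
    stop("frame must be preprocessed before segmentation")
  }
  if (!is.null(model$grid) && !grids_equal(model$grid, frame$cube$grid)) {
    stop("frame wavelength grid does not match the trained model")
  }
  check_cnn_input(model, dim(frame$cube$intensities))
  scores <- .cnn_forward_cpp(frame$cube$intensities, model$weights)
  segmentation_result(scores,
                      decision = matrix(as.integer(scores[, , 2] >
                                                     scores[, , 1]),
                                        dim(scores)[1], dim(scores)[2]))
}
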