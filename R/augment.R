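#' Blur every channel with a k x k mean filter
#'
#' Uniform box ("window") filter with edge replication, applied channel by
#' channel. Part of the photometric augmentation menu (window sizes 3, 5, 7).
#'
#' @param cube An [mwpa_cube()].
#' @param k Odd window size in `{3, 5, 7}`.
#' @return Blurred cube, same shape and state.
#' @export
blur_cube <- function(cube, k) {
  stopifnot(inherits(cube, "mwpa_cube"))
  if (k %% 2 != 1 || !(k %in% c(3, 5, 7))) {
    stop("blur window must be odd and one of 3, 5, 7")
  }
  cube$intensities <- .box_blur_cpp(cube$intensities, as.integer(k))
  cube
}

#' Corrupt a cube with additive Gaussian noise
#'
#' I.i.d. zero-mean Gaussian noise per element, clipped at zero so the
#' result remains a valid intensity cube. Deterministic given the seed.
#'
#' @param cube An [mwpa_cube()].
#' @param sigma Noise standard deviation (> 0), on the cube's intensity
#'   scale.
#' @param seed Random seed.
#' @return Noisy cube, same shape and state.
#' @export
corrupt_noise <- function(cube, sigma, seed) {
  stopifnot(inherits(cube, "mwpa_cube"), sigma > 0)
  v <- cube$intensities
  withr::with_seed(seed, {
    v <- v + array(stats::rnorm(length(v), sd = sigma), dim = dim(v))
  })
  v[v < 0] <- 0
  # like blur, noise may leave pixel maxima below 1 on a normalized cube;
  # augmented variants are training inputs, not re-normalized
  cube$intensities <- v
  cube
}

flip_ud_mat <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
flip_lr_mat <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

transform_frame <- function(frame, fr, fc) {
  tr <- function(m) {
    if (fr) m <- flip_ud_mat(m)
    if (fc) m <- flip_lr_mat(m)
    m
  }
  v <- frame$cube$intensities
  for (i in seq_len(dim(v)[3])) v[, , i] <- tr(v[, , i])
  frame$cube$intensities <- v
  frame$us$intensities <- tr(frame$us$intensities)
  frame$mask <- label_mask(tr(unclass(frame$mask)))
  frame
}

#' Geometric variants of a frame
#'
#' Returns the identity, upside-down flip, left-right flip and 180-degree
#' rotation of a frame, applied consistently to cube, ultrasound image and
#' mask.
#'
#' @param frame A [pa_frame()].
#' @return Named list of 4 frames: `identity`, `flip_ud`, `flip_lr`,
#'   `rot180`.
#' @export
geometric_variants <- function(frame) {
  list(identity = frame,
       flip_ud = transform_frame(frame, TRUE, FALSE),
       flip_lr = transform_frame(frame, FALSE, TRUE),
       rot180 = transform_frame(frame, TRUE, TRUE))
}

#' The x24 training-set augmentation
#'
#' Each input frame yields 6 photometric variants (original, two independent
#' Gaussian-noise draws, and 3/5/7-pixel box blurs), each in 4 geometric
#' orientations, for 24 outputs per input. Masks follow the geometric
#' transform of their cube and are never altered photometrically.
#'
#' @param frames Nonempty list of [pa_frame()].
#' @param sigma Noise standard deviation; default 5% of the normalized
#'   dynamic range.
#' @param seed Master seed for the noise draws.
#' @return List of `24 * length(frames)` frames.
#' @export
augment_set <- function(frames, sigma = 0.05, seed = 1L) {
  stopifnot(length(frames) > 0)
  out <- vector("list", 24L * length(frames))
  idx <- 1L
  for (f in seq_along(frames)) {
    frame <- frames[[f]]
    s1 <- (seed + 2L * f - 1L) %% .Machine$integer.max
    s2 <- (seed + 2L * f) %% .Machine$integer.max
    photometric <- list(
      frame,
      { fr <- frame; fr$cube <- corrupt_noise(frame$cube, sigma, s1); fr },
      { fr <- frame; fr$cube <- corrupt_noise(frame$cube, sigma, s2); fr },
      { fr <- frame; fr$cube <- blur_cube(frame$cube, 3); fr },
      { fr <- frame; fr$cube <- blur_cube(frame$cube, 5); fr },
      { fr <- frame; fr$cube <- blur_cube(frame$cube, 7); fr })
    for (p in photometric) {
      for (g in geometric_variants(p)) {
        out[[idx]] <- g
        idx <- idx + 1L
      }
    }
  }
  out
}
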