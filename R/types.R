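#' Label-mask codes
#'
#' Ternary per-pixel ground truth: `UNLABELED` pixels (boundary bands, water)
#' carry zero training weight and are excluded from all metrics.
#' @name mask-codes
#' @export
MASK_UNLABELED <- 0L
#' @rdname mask-codes
#' @export
MASK_NON_ABLATED <- 1L
#' @rdname mask-codes
#' @export
MASK_ABLATED <- 2L

CUBE_STATES <- c("raw", "fluence_normalized", "max_normalized")

#' MWPA image cube
#'
#' An H x W x Lambda array of photoacoustic intensities, one channel per
#' optical wavelength, together with its wavelength grid, spatial sampling
#' and provenance state (`raw`, `fluence_normalized` or `max_normalized`).
#'
#' @param intensities Numeric H x W x Lambda array, finite; non-negative for
#'   raw and fluence-normalized cubes.
#' @param grid A [make_grid()] wavelength grid; its length must equal
#'   `dim(intensities)[3]`.
#' @param pixel_pitch_um Spatial sampling (micrometres per pixel).
#' @param state Provenance state.
#' @return An `mwpa_cube`.
#' @export
mwpa_cube <- function(intensities, grid, pixel_pitch_um = 73.92,
                      state = "raw") {
  state <- match.arg(state, CUBE_STATES)
  if (length(dim(intensities)) != 3) stop("intensities must be a 3-D array")
  if (dim(intensities)[3] != length(grid$values)) {
    stop(sprintf("cube has %d channels but grid has %d wavelengths",
                 dim(intensities)[3], length(grid$values)))
  }
  if (any(!is.finite(intensities))) stop("intensities must be finite")
  if (state != "max_normalized" && any(intensities < 0)) {
    stop("negative intensities in a ", state, " cube")
  }
  structure(
    list(intensities = intensities, grid = grid,
         pixel_pitch_um = pixel_pitch_um, state = state),
    class = "mwpa_cube")
}

#' @export
dim.mwpa_cube <- function(x) dim(x$intensities)

#' @export
print.mwpa_cube <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<mwpa_cube> %d x %d x %d (%s), pitch %.2f um\n",
              d[1], d[2], d[3], x$state, x$pixel_pitch_um))
  invisible(x)
}

#' Co-registered single-channel ultrasound image
#'
#' @param intensities Non-negative H x W matrix.
#' @param pixel_pitch_um Spatial sampling (micrometres per pixel).
#' @return A `us_image`.
#' @export
us_image <- function(intensities, pixel_pitch_um = 73.92) {
  stopifnot(is.matrix(intensities), all(intensities >= 0))
  structure(list(intensities = intensities, pixel_pitch_um = pixel_pitch_um),
            class = "us_image")
}

#' Ternary label mask
#'
#' @param codes Integer H x W matrix over `{MASK_UNLABELED,
#'   MASK_NON_ABLATED, MASK_ABLATED}`.
#' @return A `label_mask` (an integer matrix with class attribute).
#' @export
label_mask <- function(codes) {
  stopifnot(is.matrix(codes))
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(MASK_UNLABELED, MASK_NON_ABLATED, MASK_ABLATED))) {
    stop("mask codes must be in {0 = unlabeled, 1 = non-ablated, 2 = ablated}")
  }
  structure(codes, class = c("label_mask", "matrix", "array"))
}

#' Per-wavelength laser pulse-energy spectrum
#'
#' The laser fluence F(lambda) measured at the fiber output, used by
#' [normalize_fluence()].
#'
#' @param grid Wavelength grid.
#' @param energy_mJ Strictly positive pulse energies (mJ), one per
#'   wavelength.
#' @return A `fluence_spectrum`.
#' @export
fluence_spectrum <- function(grid, energy_mJ) {
  if (length(energy_mJ) != length(grid$values)) {
    stop("energy vector length must equal grid length")
  }
  if (any(energy_mJ <= 0)) stop("pulse energy must be strictly positive")
  structure(list(grid = grid, energy_mJ = as.numeric(energy_mJ)),
            class = "fluence_spectrum")
}

#' One co-registered acquisition frame
#'
#' Bundles an MWPA cube, its ultrasound backdrop, the ternary label mask,
#' the tissue-block identifier and the number of lesions present.
#'
#' @param cube An [mwpa_cube()].
#' @param us A [us_image()] with the same H x W.
#' @param mask A [label_mask()] with the same H x W.
#' @param block_id Tissue-block identifier.
#' @param n_lesions Integer 0--3.
#' @return A `pa_frame`.
#' @export
pa_frame <- function(cube, us, mask, block_id, n_lesions) {
  d <- dim(cube$intensities)
  if (!all(dim(us$intensities) == d[1:2])) stop("US image H x W mismatch")
  if (!all(dim(mask) == d[1:2])) stop("mask H x W mismatch")
  stopifnot(n_lesions >= 0, n_lesions <= 3)
  structure(list(cube = cube, us = us, mask = mask,
                 block_id = block_id, n_lesions = as.integer(n_lesions)),
            class = "pa_frame")
}

#' @export
print.pa_frame <- function(x, ...) {
  d <- dim(x$cube$intensities)
  cat(sprintf("<pa_frame> block %s, %d lesion(s), %d x %d x %d (%s)\n",
              x$block_id, x$n_lesions, d[1], d[2], d[3], x$cube$state))
  invisible(x)
}

#' Per-pixel segmentation output
#'
#' @param scores H x W x 2 per-class score array (channel 1 = non-ablated,
#'   channel 2 = ablated).
#' @param decision Optional H x W 0/1 matrix; computed as the per-pixel
#'   argmax with ties resolved to non-ablated when omitted.
#' @return A `segmentation_result`.
#' @export
segmentation_result <- function(scores, decision = NULL) {
  stopifnot(length(dim(scores)) == 3, dim(scores)[3] == 2)
  if (is.null(decision)) {
    decision <- (scores[, , 2] > scores[, , 1]) * 1L
  }
  storage.mode(decision) <- "integer"
  stopifnot(all(dim(decision) == dim(scores)[1:2]))
  structure(list(scores = scores, decision = decision),
            class = "segmentation_result")
}

#' Number of connected ablated regions in a mask (4-connectivity)
#'
#' @param mask A [label_mask()].
#' @return Integer count of connected `MASK_ABLATED` components.
#' @export
count_lesions <- function(mask) {
  lab <- label_components(unclass(mask) == MASK_ABLATED)
  max(lab)
}

# two-pass-free flood fill labelling of a logical matrix, 4-connectivity
label_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (p - 1L) %% h + 1L
      c <- (p - 1L) %/% h + 1L
      for (q in c(if (r > 1) p - 1L, if (r < h) p + 1L,
                  if (c > 1) p - h, if (c < w) p + h)) {
        if (m[q] && lab[q] == 0L) {
          lab[q] <- nxt
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}
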