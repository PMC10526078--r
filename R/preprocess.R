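#' Normalize a raw cube to the laser fluence
#'
#' Divides every channel by the measured pulse energy F(lambda), removing
#' the wavelength dependence introduced by the laser output. First of the
#' two preprocessing steps; operates on raw cubes only.
#'
#' @param cube A raw-state [mwpa_cube()].
#' @param fluence A [fluence_spectrum()] on the same grid.
#' @return A `fluence_normalized` cube of the same shape.
#' @export
normalize_fluence <- function(cube, fluence) {
  stopifnot(inherits(cube, "mwpa_cube"), inherits(fluence, "fluence_spectrum"))
  if (cube$state != "raw") {
    stop("normalize_fluence expects a raw cube, got state ", cube$state)
  }
  if (!grids_equal(cube$grid, fluence$grid)) {
    stop("cube and fluence wavelength grids differ")
  }
  if (any(fluence$energy_mJ <= 0)) stop("non-positive fluence")
  v <- cube$intensities
  v <- sweep(v, 3, fluence$energy_mJ, "/")
  mwpa_cube(v, cube$grid, cube$pixel_pitch_um, state = "fluence_normalized")
}

#' Normalize each pixel spectrum to its own maximum
#'
#' Divides every pixel's spectrum by its maximum element, yielding a
#' normalized absorption-spectrum representation bounded in `[0, 1]` that is
#' invariant to any positive per-pixel scale (system sensitivity, Grueneisen
#' coefficient, global fluence). All-zero pixels stay all-zero.
#'
#' @param cube A `fluence_normalized` (or already `max_normalized`)
#'   [mwpa_cube()].
#' @return A `max_normalized` cube.
#' @export
normalize_max <- function(cube) {
  stopifnot(inherits(cube, "mwpa_cube"))
  if (cube$state == "raw") {
    stop("normalize_max expects a fluence-normalized cube; ",
         "apply normalize_fluence first")
  }
  v <- cube$intensities
  v[v < 0] <- 0
  d <- dim(v)
  m <- matrix(v, d[1] * d[2], d[3])
  mx <- do.call(pmax, c(as.data.frame(m), list(0)))
  # divide (not multiply by a reciprocal): the maximum element maps to
  # exactly 1 and the operation is bit-exact idempotent
  v <- array(m / ifelse(mx > 0, mx, 1), dim = d)
  mwpa_cube(v, cube$grid, cube$pixel_pitch_um, state = "max_normalized")
}

#' Preprocess a frame
#'
#' The two-step spectral normalization: first divide each channel by the
#' laser pulse energy, then divide each pixel spectrum by its own maximum.
#' Ultrasound image and label mask are untouched.
#'
#' @param frame A [pa_frame()] with a raw cube.
#' @param fluence A [fluence_spectrum()].
#' @return The frame with a `max_normalized` cube.
#' @export
preprocess_frame <- function(frame, fluence) {
  stopifnot(inherits(frame, "pa_frame"))
  frame$cube <- normalize_max(normalize_fluence(frame$cube, fluence))
  frame
}

#' @rdname preprocess_frame
#' @param frames List of [pa_frame()].
#' @export
preprocess_frames <- function(frames, fluence) {
  lapply(frames, preprocess_frame, fluence = fluence)
}
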