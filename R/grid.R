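#' Construct a wavelength grid
#'
#' The imaging wavelengths of a multi-wavelength photoacoustic (MWPA)
#' acquisition, e.g. 690--950 nm in 5-nm steps giving 53 channels. The grid
#' orders channels by ascending wavelength; channel `k` (1-based) sits at
#' `start_nm + (k - 1) * step_nm`.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must satisfy
#'   `stop_nm >= start_nm` and `(stop_nm - start_nm) %% step_nm == 0`.
#' @param step_nm Positive wavelength increment (nm).
#' @return A `wavelength_grid` object with fields `start_nm`, `stop_nm`,
#'   `step_nm` and `values`.
#' @examples
#' g <- make_grid(690, 950, 5)
#' length(g$values)  # 53
#' @export
make_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) stop("step_nm must be > 0")
  if (stop_nm < start_nm) stop("stop_nm must be >= start_nm")
  rem <- (stop_nm - start_nm) %% step_nm
  if (abs(rem) > 1e-9 && abs(rem - step_nm) > 1e-9) {
    stop(sprintf(
      "wavelength range (%g, %g) is not divisible by step %g (remainder %g)",
      start_nm, stop_nm, step_nm, rem))
  }
  values <- seq(start_nm, stop_nm, by = step_nm)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         values = values),
    class = "wavelength_grid")
}

#' Build a grid from an explicit (possibly irregular) wavelength vector
#'
#' Used when channels are subset to a non-uniform set (e.g. the most
#' important wavelengths found by sequential selection). For irregular
#' spacing `step_nm` is `NA`.
#'
#' @param values_nm Strictly increasing wavelengths (nm).
#' @return A `wavelength_grid`.
#' @export
grid_from_values <- function(values_nm) {
  values_nm <- as.numeric(values_nm)
  if (length(values_nm) == 0) stop("empty wavelength set")
  if (any(diff(values_nm) <= 0)) {
    stop("wavelengths must be strictly increasing with no duplicates")
  }
  steps <- unique(diff(values_nm))
  step <- if (length(steps) == 1) steps else NA_real_
  if (length(values_nm) == 1) step <- NA_real_
  structure(
    list(start_nm = values_nm[1], stop_nm = values_nm[length(values_nm)],
         step_nm = step, values = values_nm),
    class = "wavelength_grid")
}

#' @export
length.wavelength_grid <- function(x) length(x$values)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %d wavelengths, %g-%g nm%s\n",
              length(x$values), x$start_nm, x$stop_nm,
              if (is.na(x$step_nm)) " (irregular)"
              else sprintf(", step %g nm", x$step_nm)))
  invisible(x)
}

grids_equal <- function(a, b) {
  length(a$values) == length(b$values) &&
    all(abs(a$values - b$values) < 1e-9)
}

#' Ideal acquisition frame rate
#'
#' Frame rate achievable for an `n_wavelengths`-channel MWPA frame with a
#' pulsed laser firing at `rep_rate_hz` and `firings_per_wavelength` laser
#' shots needed per wavelength (two when receive channels are 2:1
#' multiplexed), with no signal averaging.
#'
#' @param n_wavelengths Wavelengths per frame.
#' @param rep_rate_hz Laser repetition rate (Hz), default 20.
#' @param firings_per_wavelength Laser firings per wavelength, default 2.
#' @return Frames per second.
#' @examples
#' acquisition_rate(1)  # 10 FPS single-wavelength
#' acquisition_rate(2)  # 5 FPS dual-wavelength
#' @export
acquisition_rate <- function(n_wavelengths, rep_rate_hz = 20,
                             firings_per_wavelength = 2) {
  stopifnot(n_wavelengths >= 1)
  rep_rate_hz / (firings_per_wavelength * n_wavelengths)
}
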