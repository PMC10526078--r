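#' Greedy sequential forward wavelength selection
#'
#' Starting from an empty set, repeatedly adds the wavelength whose
#' provisional addition gives the lowest held-out error of a quadratic
#' classifier, until no addition lowers the error (or `max_k` wavelengths
#' are selected). The pixel data are shuffled once into a 90% train / 10%
#' test split; earlier-selected wavelengths are the more important ones.
#'
#' @param dataset A [pixel_dataset] with both classes and at least 2
#'   wavelengths (unless `max_k = 1`).
#' @param seed Seed for the shuffled split.
#' @param max_k Optional cap on the number of selected wavelengths.
#' @param test_frac Held-out fraction (default 0.1).
#' @return A `selection_trace`: list with `order` (wavelengths nm, most
#'   important first), `errors` (strictly decreasing test error after each
#'   addition), `stop_reason` (`"no improvement"` or `"exhausted"`), and —
#'   when a finite `max_k` asks for more wavelengths than the trace
#'   contains — `extended_order`, the greedy importance ranking continued
#'   past the stopping point (used to subset cubes when the natural trace
#'   is shorter than a requested reduced set).
#' @export
sequential_select <- function(dataset, seed = 1L, max_k = Inf,
                              test_frac = 0.1) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  X <- dataset$features
  y <- dataset$labels
  if (length(unique(y)) < 2) stop("both classes required")
  n <- nrow(X)
  test <- withr::with_seed(seed, sample(n, max(1, round(test_frac * n))))
  tr <- setdiff(seq_len(n), test)
  wl <- dataset$grid$values

  selected <- integer(0)
  extended <- integer(0)
  errors <- numeric(0)
  best_err <- Inf
  stop_reason <- "exhausted"
  stopped <- FALSE
  while (length(extended) < min(ncol(X), max_k)) {
    candidates <- setdiff(seq_len(ncol(X)), extended)
    errs <- vapply(candidates, function(j) {
      cols <- c(extended, j)
      fit <- qda_fit(X[tr, cols, drop = FALSE], y[tr], ridge = 1e-8)
      mean(qda_predict(fit, X[test, cols, drop = FALSE]) != y[test])
    }, 0)
    # tie-break: among equal-error candidates take the shortest wavelength
    best <- candidates[order(errs, wl[candidates])][1]
    if (!stopped && min(errs) >= best_err) {
      stop_reason <- "no improvement"
      stopped <- TRUE
      # the recorded trace ends here; keep ranking further wavelengths by
      # the same greedy rule only if a longer importance order was asked
      # for explicitly (max_k beyond the trace)
      if (!is.finite(max_k)) break
    }
    if (!stopped) {
      best_err <- min(errs)
      selected <- c(selected, best)
      errors <- c(errors, best_err)
    }
    extended <- c(extended, best)
  }
  structure(list(order = wl[selected], order_index = selected,
                 errors = errors, stop_reason = stop_reason,
                 extended_order = wl[extended],
                 extended_index = extended),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d wavelength(s), error %.4f -> %.4f (%s)\n",
              length(x$order),
              if (length(x$errors)) x$errors[1] else NA_real_,
              if (length(x$errors)) x$errors[length(x$errors)] else NA_real_,
              x$stop_reason))
  invisible(x)
}

#' Class-mean spectra and their ratio
#'
#' Average normalized spectrum of the ablated and non-ablated pixels, and
#' the ablated:non-ablated ratio used to see where the two classes differ
#' most (it peaks where selection finds the important wavelengths).
#'
#' @param dataset A [pixel_dataset] with both classes present.
#' @return List with `wavelength_nm`, `ablated`, `non_ablated`, `ratio`.
#' @export
mean_spectra <- function(dataset) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  if (!any(dataset$labels == 1) || !any(dataset$labels == 0)) {
    stop("both classes must be present")
  }
  abl <- colMeans(dataset$features[dataset$labels == 1, , drop = FALSE])
  non <- colMeans(dataset$features[dataset$labels == 0, , drop = FALSE])
  list(wavelength_nm = dataset$grid$values, ablated = abl,
       non_ablated = non, ratio = abl / non)
}

#' Restrict a cube to a wavelength subset
#'
#' Channels are re-ordered ascending by wavelength. A max-normalized cube is
#' re-normalized over the remaining channels so the reduced cube is
#' preprocessed exactly like a natively reduced acquisition.
#'
#' @param cube An [mwpa_cube()].
#' @param wavelengths_nm Wavelengths to keep; all must be on the cube grid.
#' @return The reduced [mwpa_cube()].
#' @export
subset_cube <- function(cube, wavelengths_nm) {
  stopifnot(inherits(cube, "mwpa_cube"))
  wl <- sort(unique(as.numeric(wavelengths_nm)))
  idx <- match(wl, cube$grid$values)
  if (anyNA(idx)) {
    stop("wavelength(s) not on the cube grid: ",
         paste(wl[is.na(idx)], collapse = ", "))
  }
  out <- mwpa_cube(cube$intensities[, , idx, drop = FALSE],
                   grid_from_values(wl), cube$pixel_pitch_um,
                   state = if (cube$state == "max_normalized")
                     "fluence_normalized" else cube$state)
  if (cube$state == "max_normalized") out <- normalize_max(out)
  out
}

#' @rdname subset_cube
#' @param frame A [pa_frame()].
#' @export
subset_frame <- function(frame, wavelengths_nm) {
  frame$cube <- subset_cube(frame$cube, wavelengths_nm)
  frame
}
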