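#' Write / read an MWPA cube as HDF5
#'
#' Cubes are stored in an HDF5 container with datasets `intensities`
#' (H x W x Lambda, float64), `wavelengths_nm`, `pixel_pitch_um` and `state`.
#' Channel order on disk is ascending wavelength. A write/read round trip
#' reproduces the intensity array bit-exactly.
#'
#' @param cube An [mwpa_cube()].
#' @param path Output `.h5` path (overwritten if present).
#' @return `write_cube()` returns `path` invisibly; `read_cube()` returns an
#'   [mwpa_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "mwpa_cube"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$intensities, path, "intensities")
  rhdf5::h5write(cube$grid$values, path, "wavelengths_nm")
  rhdf5::h5write(cube$pixel_pitch_um, path, "pixel_pitch_um")
  rhdf5::h5write(cube$state, path, "state")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  contents <- rhdf5::h5ls(path)$name
  needed <- c("intensities", "wavelengths_nm", "pixel_pitch_um", "state")
  missing <- setdiff(needed, contents)
  if (length(missing)) {
    stop("cube file ", path, " is missing dataset(s): ",
         paste(missing, collapse = ", "))
  }
  intens <- rhdf5::h5read(path, "intensities")
  wl <- as.numeric(rhdf5::h5read(path, "wavelengths_nm"))
  pitch <- as.numeric(rhdf5::h5read(path, "pixel_pitch_um"))
  state <- as.character(rhdf5::h5read(path, "state"))
  rhdf5::h5closeAll()
  if (length(dim(intens)) != 3 || dim(intens)[3] != length(wl)) {
    stop(sprintf("cube file has %d channel page(s) but %d wavelengths",
                 if (length(dim(intens)) == 3) dim(intens)[3] else -1L,
                 length(wl)))
  }
  mwpa_cube(intens, grid_from_values(wl), pitch, state)
}

#' Write / read a ternary label mask as 8-bit grayscale PNG
#'
#' Pixel byte values are the mask codes themselves: 0 = unlabeled,
#' 1 = non-ablated, 2 = ablated. Any other byte is rejected on read.
#'
#' @param mask A [label_mask()].
#' @param path Output `.png` path.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a
#'   [label_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  codes <- round(img * 255)
  if (!all(codes %in% 0:2)) {
    stop("mask file contains pixel value(s) outside {0, 1, 2}")
  }
  label_mask(matrix(as.integer(codes), nrow(codes), ncol(codes)))
}

#' Write / read a laser pulse-energy spectrum as CSV
#'
#' Plain CSV with header `wavelength_nm,energy_mJ`.
#'
#' @param fluence A [fluence_spectrum()].
#' @param path CSV path.
#' @return `read_fluence()` returns a [fluence_spectrum()].
#' @export
write_fluence <- function(fluence, path) {
  stopifnot(inherits(fluence, "fluence_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = fluence$grid$values,
               energy_mJ = fluence$energy_mJ),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "energy_mJ") %in% names(df))) {
    stop("fluence CSV must have columns wavelength_nm,energy_mJ")
  }
  fluence_spectrum(grid_from_values(df$wavelength_nm), df$energy_mJ)
}

#' Physical extent of an image axis
#'
#' @param n_px Pixel count along the axis.
#' @param pixel_pitch_um Pixel pitch (micrometres).
#' @return Extent in centimetres (512 px at 73.92 um is 3.78 cm).
#' @export
view_extent_cm <- function(n_px, pixel_pitch_um = 73.92) {
  n_px * pixel_pitch_um * 1e-4
}
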