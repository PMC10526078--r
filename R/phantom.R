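#' Default chromophore-like absorption spectra
#'
#' Non-ablated tissue follows a deoxyhemoglobin-like shape: a local feature
#' near 757 nm on top of a declining near-infrared baseline. Coagulative
#' necrosis destroys that hemoglobin feature and adds a broader elevation
#' centered near 775 nm (plus a modest overall increase), so the
#' ablated:non-ablated ratio peaks inside the 720--790 nm window while the
#' *normalized* spectra of the two classes nearly coincide at the band
#' edges — the class contrast is localized, which is what makes wavelength
#' selection concentrate on the 760--790 nm channels.
#'
#' @param grid Wavelength grid.
#' @return Numeric vector of absorption coefficients (1/cm).
#' @export
mu_abs_nonablated_default <- function(grid) {
  l <- grid$values
  0.28 * exp(-(l - 690) / 85) + 0.08 + 0.18 * exp(-((l - 757) / 22)^2)
}

#' @rdname mu_abs_nonablated_default
#' @export
mu_abs_ablated_default <- function(grid) {
  l <- grid$values
  1.25 * (0.28 * exp(-(l - 690) / 85) + 0.08 +
            0.20 * exp(-((l - 775) / 30)^2))
}

#' Default laser pulse-energy spectrum
#'
#' Smooth positive curve anchored at 14.74 mJ (715 nm peak) and 7.93 mJ
#' (950 nm), emulating a tunable OPO laser output.
#'
#' @param grid Wavelength grid.
#' @return A [fluence_spectrum()].
#' @export
default_fluence <- function(grid) {
  l <- grid$values
  g950 <- exp(-((950 - 715) / 110)^2)
  b <- (14.74 - 7.93) / (1 - g950)
  a <- 14.74 - b
  fluence_spectrum(grid, a + b * exp(-((l - 715) / 110)^2))
}

#' Phantom configuration
#'
#' Parameters of the synthetic MWPA forward model
#' `v = E(r) * Gamma * mu_abs(r, lambda) * F(lambda) *
#' exp(-mu_eff(lambda) * depth(r)) + N`. Defaults describe the full-size
#' acquisition geometry (512 x 339 pixels at 73.92 um pitch, 53 wavelengths
#' 690--950 nm); [reduced_phantom_config()] gives a desk-scale view of the
#' same physical scene.
#'
#' @param grid Wavelength grid.
#' @param height_px,width_px Frame dimensions (rows = depth axis, row 1 is
#'   shallowest).
#' @param pixel_pitch_um Spatial sampling (um).
#' @param mu_abs_nonablated,mu_abs_ablated Per-wavelength absorption (1/cm);
#'   the ablated:non-ablated ratio must peak within 720--790 nm.
#' @param grueneisen Grueneisen coefficient (dimensionless scalar).
#' @param sensitivity_amp Amplitude of the smooth multiplicative system
#'   sensitivity field E(r) (mean 1).
#' @param mu_eff Per-wavelength effective attenuation (1/cm) governing the
#'   Beer-Lambert fluence decay with depth.
#' @param fluence A [fluence_spectrum()], F(lambda).
#' @param noise_sigma Additive Gaussian noise standard deviation (system
#'   units); negative renders are clipped to zero.
#' @param spectrum_jitter_cv Per-pixel multiplicative spectral variation
#'   (lognormal coefficient of variation).
#' @param water_depth_mm Depth of the tissue surface below the image top.
#' @param lesion_depth_mm Depth of lesion centers.
#' @param lesion_axes_mm Lesion semi-axes, `c(axial, lateral)` (mm).
#' @param lesion_offsets_mm Lateral lesion-center offsets from the frame
#'   centerline for lesions 1..3 (mm).
#' @param boundary_band_px Lateral half-width (pixels) of the unlabeled band
#'   around lesion boundaries; the axial half-width is twice this, since
#'   axial lesion extent is the less certain direction.
#' @param sidelobe Enable imaging/tissue artifacts: lesion-flanking
#'   side-lobe satellites carrying a partially ablated spectrum (left
#'   unlabeled, as their status is uncertain) and scattered single-pixel
#'   confuser specks in background tissue (fat marbling / off-plane
#'   artifacts) whose spectrum is drawn from the ablated distribution but
#'   which are labeled non-ablated. The specks bound the precision of any
#'   per-pixel classifier while remaining invisible to a segmenter that
#'   uses spatial context.
#' @param sidelobe_amp Spectral blend factor of the flanking satellites,
#'   0--1.
#' @param speck_rate Per-pixel probability of a confuser speck in
#'   background tissue (only when `sidelobe` is enabled).
#' @param seed Default random seed for scene/render operations.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(grid = make_grid(690, 950, 5),
                           height_px = 339, width_px = 512,
                           pixel_pitch_um = 73.92,
                           mu_abs_nonablated = mu_abs_nonablated_default(grid),
                           mu_abs_ablated = mu_abs_ablated_default(grid),
                           grueneisen = 1,
                           sensitivity_amp = 0.15,
                           mu_eff = 1.5 - 0.3 * (grid$values - 690) / 260,
                           fluence = default_fluence(grid),
                           noise_sigma = 0.02,
                           spectrum_jitter_cv = 0.10,
                           water_depth_mm = 4,
                           lesion_depth_mm = 12,
                           lesion_axes_mm = c(axial = 2.5, lateral = 1.5),
                           lesion_offsets_mm = c(-5, 0, 5),
                           boundary_band_px = 4,
                           sidelobe = TRUE,
                           sidelobe_amp = 0.6,
                           speck_rate = 0.004,
                           seed = 1L) {
  stopifnot(length(mu_abs_nonablated) == length(grid$values),
            length(mu_abs_ablated) == length(grid$values),
            all(mu_abs_nonablated > 0), all(mu_abs_ablated > 0),
            grueneisen > 0, noise_sigma >= 0, boundary_band_px >= 0,
            length(mu_eff) == length(grid$values))
  if (!grids_equal(fluence$grid, grid)) stop("fluence grid mismatch")
  stopifnot(length(lesion_axes_mm) == 2, all(lesion_axes_mm > 0))
  names(lesion_axes_mm) <- c("axial", "lateral")
  ratio <- mu_abs_ablated / mu_abs_nonablated
  peak <- grid$values[which.max(ratio)]
  spans_window <- grid$start_nm <= 720 && grid$stop_nm >= 790
  if (spans_window && (peak < 720 || peak > 790)) {
    stop("ablated:non-ablated absorption ratio must peak in 720-790 nm, ",
         "peaks at ", peak, " nm")
  }
  structure(
    list(grid = grid, height_px = height_px, width_px = width_px,
         pixel_pitch_um = pixel_pitch_um,
         mu_abs_nonablated = mu_abs_nonablated,
         mu_abs_ablated = mu_abs_ablated,
         grueneisen = grueneisen, sensitivity_amp = sensitivity_amp,
         mu_eff = mu_eff, fluence = fluence, noise_sigma = noise_sigma,
         spectrum_jitter_cv = spectrum_jitter_cv,
         water_depth_mm = water_depth_mm,
         lesion_depth_mm = lesion_depth_mm,
         lesion_axes_mm = lesion_axes_mm,
         lesion_offsets_mm = lesion_offsets_mm,
         boundary_band_px = boundary_band_px,
         sidelobe = sidelobe, sidelobe_amp = sidelobe_amp,
         speck_rate = speck_rate,
         seed = as.integer(seed)),
    class = "phantom_config")
}

#' Desk-scale phantom configuration
#'
#' Same physical scene as the full geometry but sampled on a 96 x 128 grid
#' (pixel pitch scaled by 4 so the +/-5 mm lesion layout still fits the
#' view). Used by the test suite and experiment defaults.
#'
#' @param ... Overrides passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
reduced_phantom_config <- function(...) {
  args <- list(height_px = 96, width_px = 128, pixel_pitch_um = 73.92 * 4)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_config, args)
}

#' Build a phantom scene
#'
#' Lays out a water layer above a tissue block and up to three elliptical
#' lesions centered at the configured lateral offsets and focal depth, draws
#' the per-block system sensitivity field E(r) and the per-pixel jittered
#' absorption field mu_abs(r, lambda).
#'
#' @param config A [phantom_config()].
#' @param n_lesions Integer 0--3; lesion k sits at `lesion_offsets_mm[k]`.
#' @param seed Random seed (defaults to `config$seed`). Scenes with the same
#'   seed share the sensitivity field and background jitter regardless of
#'   lesion count.
#' @return A `phantom_scene` with `tissue_map` (0 water, 1 tissue,
#'   1 + k lesion k), `depth_map` (cm), `mu_abs_field`, `sensitivity`,
#'   `sidelobe_map`.
#' @export
build_scene <- function(config, n_lesions, seed = config$seed) {
  stopifnot(n_lesions >= 0, n_lesions <= 3,
            n_lesions <= length(config$lesion_offsets_mm))
  h <- config$height_px; w <- config$width_px
  pitch_mm <- config$pixel_pitch_um * 1e-3
  withr::with_seed(seed, {
    # smooth multiplicative sensitivity field, mean ~1 (drawn first so it is
    # identical across frames of a block regardless of lesion count)
    raw <- array(stats::rnorm(h * w), dim = c(h, w, 1))
    sm <- .box_blur_cpp(raw, 2L * (min(h, w) %/% 8) + 1L)[, , 1]
    sm <- (sm - mean(sm)) / max(stats::sd(sm), 1e-12)
    sens <- 1 + config$sensitivity_amp * sm
    sens[sens < 0.1] <- 0.1
    nl <- length(config$grid$values)
    # spectrally smooth per-pixel variation: tissue heterogeneity varies
    # slowly with wavelength, so log-jitter is drawn on coarse spectral
    # knots and interpolated across channels (neighboring channels are
    # therefore redundant, as in real spectra)
    n_knots <- max(2L, ceiling(nl / 8))
    knots <- matrix(stats::rnorm(h * w * n_knots), h * w, n_knots)
    speck_draw <- matrix(stats::runif(h * w), h, w)
  })
  if (nl == 1) {
    jitter <- array(exp(config$spectrum_jitter_cv * knots[, 1]),
                    dim = c(h, w, 1))
    knot_pos <- NULL
  } else {
  knot_pos <- seq(1, nl, length.out = n_knots)
  interp <- t(vapply(seq_len(nl), function(i) {
    j <- findInterval(i, knot_pos, rightmost.closed = TRUE)
    j <- min(j, n_knots - 1L)
    t <- (i - knot_pos[j]) / (knot_pos[j + 1] - knot_pos[j])
    w0 <- numeric(n_knots)
    w0[j] <- 1 - t
    w0[j + 1] <- t
    w0
  }, numeric(n_knots)))
  jitter <- array(exp(config$spectrum_jitter_cv *
                        tcrossprod(knots, interp)),
                  dim = c(h, w, nl))
  }

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  depth_mm <- (rows - 0.5) * pitch_mm
  tissue_map <- matrix(1L, h, w)
  tissue_map[depth_mm < config$water_depth_mm] <- 0L

  ax <- config$lesion_axes_mm["axial"]
  lat <- config$lesion_axes_mm["lateral"]
  center_col_mm <- (w / 2) * pitch_mm
  inside_ellipse <- function(c_mm, d_mm, a_mm, l_mm) {
    ((depth_mm - d_mm) / a_mm)^2 +
      ((cols - 0.5) * pitch_mm - c_mm)^2 / l_mm^2 <= 1
  }
  sidelobe_map <- matrix(FALSE, h, w)
  for (k in seq_len(n_lesions)) {
    c_mm <- center_col_mm + config$lesion_offsets_mm[k]
    if (c_mm - lat < 0 || c_mm + lat > w * pitch_mm ||
        config$lesion_depth_mm - ax < config$water_depth_mm ||
        config$lesion_depth_mm + ax > h * pitch_mm) {
      stop("lesion ", k, " extends beyond the frame/tissue region")
    }
    les <- inside_ellipse(c_mm, config$lesion_depth_mm, ax, lat)
    tissue_map[les & tissue_map >= 1L] <- 1L + k
    if (isTRUE(config$sidelobe)) {
      for (s in c(-1, 1)) {
        sl <- inside_ellipse(c_mm + s * 2.2 * lat, config$lesion_depth_mm,
                             0.5 * ax, 0.7 * lat)
        sidelobe_map <- sidelobe_map | (sl & tissue_map == 1L)
      }
    }
  }
  sidelobe_map <- sidelobe_map & tissue_map == 1L
  speck_map <- if (isTRUE(config$sidelobe) && config$speck_rate > 0) {
    speck_draw < config$speck_rate & tissue_map == 1L & !sidelobe_map
  } else {
    matrix(FALSE, h, w)
  }

  # absorption field: class spectrum x per-pixel jitter; water ~ transparent
  mu_n <- config$mu_abs_nonablated
  mu_a <- config$mu_abs_ablated
  nl <- length(mu_n)
  mu_field <- array(0, dim = c(h, w, nl))
  is_water <- tissue_map == 0L
  is_lesion <- tissue_map >= 2L
  blend <- config$sidelobe_amp
  for (i in seq_len(nl)) {
    ch <- matrix(mu_n[i], h, w)
    ch[is_lesion] <- mu_a[i]
    ch[sidelobe_map] <- (1 - blend) * mu_n[i] + blend * mu_a[i]
    ch[speck_map] <- mu_a[i]
    ch <- ch * jitter[, , i]
    ch[is_water] <- 0.005
    mu_field[, , i] <- ch
  }
  structure(
    list(tissue_map = tissue_map, depth_map = depth_mm / 10,
         mu_abs_field = mu_field, sensitivity = sens,
         sidelobe_map = sidelobe_map, speck_map = speck_map,
         n_lesions = as.integer(n_lesions),
         config_grid = config$grid),
    class = "phantom_scene")
}

#' Render the MWPA cube of a scene
#'
#' Applies the photoacoustic forward model: the pixel value is the system
#' sensitivity times the Grueneisen coefficient, the local absorption, the
#' laser fluence at that wavelength and the Beer-Lambert depth decay, plus
#' additive Gaussian noise clipped at zero.
#'
#' @param scene A [build_scene()] result.
#' @param config The [phantom_config()] used to build it.
#' @param seed Noise seed (defaults to `config$seed`).
#' @return A raw-state [mwpa_cube()].
#' @export
render_mwpa <- function(scene, config, seed = config$seed) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (!grids_equal(scene$config_grid, config$grid)) {
    stop("scene and config wavelength grids differ")
  }
  h <- config$height_px; w <- config$width_px
  nl <- length(config$grid$values)
  f <- config$fluence$energy_mJ
  v <- array(0, dim = c(h, w, nl))
  eg <- scene$sensitivity * config$grueneisen
  for (i in seq_len(nl)) {
    gamma <- exp(-config$mu_eff[i] * scene$depth_map)
    v[, , i] <- eg * scene$mu_abs_field[, , i] * f[i] * gamma
  }
  if (config$noise_sigma > 0) {
    withr::with_seed(seed, {
      v <- v + array(stats::rnorm(length(v), sd = config$noise_sigma),
                     dim = dim(v))
    })
    v[v < 0] <- 0
  }
  mwpa_cube(v, config$grid, config$pixel_pitch_um, state = "raw")
}

#' Render a speckle ultrasound backdrop
#'
#' Visualization-grade US image: multiplicative speckle over a tissue/water
#' brightness contrast. Not a physical acoustic simulation.
#'
#' @inheritParams render_mwpa
#' @return A [us_image()].
#' @export
render_us <- function(scene, config, seed = config$seed) {
  h <- config$height_px; w <- config$width_px
  base <- matrix(0.15, h, w)
  base[scene$tissue_map >= 1L] <- 0.6
  base[scene$tissue_map >= 2L] <- 0.75  # lesions mildly hyperechoic
  withr::with_seed(seed + 7L, {
    speckle <- abs(array(stats::rnorm(h * w), dim = c(h, w, 1)))
  })
  speckle <- .box_blur_cpp(speckle, 3L)[, , 1]
  us_image(base * (0.4 + speckle), config$pixel_pitch_um)
}

#' Ground-truth label mask of a scene
#'
#' Lesion interiors are ablated; tissue away from lesions is non-ablated;
#' water, side-lobe artifacts and an anisotropic band around each lesion
#' boundary (twice as wide axially as laterally, reflecting larger axial
#' uncertainty) are unlabeled.
#'
#' @inheritParams render_mwpa
#' @return A [label_mask()].
#' @export
make_mask <- function(scene, config) {
  lesion <- scene$tissue_map >= 2L
  codes <- matrix(MASK_NON_ABLATED, nrow(lesion), ncol(lesion))
  codes[scene$tissue_map == 0L] <- MASK_UNLABELED
  band_lat <- config$boundary_band_px
  if (band_lat > 0 && any(lesion)) {
    band_ax <- 2L * band_lat
    dil <- dilate_rect(lesion, band_ax, band_lat)
    codes[dil & !lesion] <- MASK_UNLABELED
  }
  codes[scene$sidelobe_map] <- MASK_UNLABELED
  codes[lesion] <- MASK_ABLATED
  label_mask(codes)
}

# binary dilation with a (2*band_ax+1) x (2*band_lat+1) rectangle
dilate_rect <- function(m, band_ax, band_lat) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (dr in -band_ax:band_ax) {
    rs <- max(1, 1 + dr):min(h, h + dr)
    rd <- max(1, 1 - dr):min(h, h - dr)
    for (dc in -band_lat:band_lat) {
      cs <- max(1, 1 + dc):min(w, w + dc)
      cd <- max(1, 1 - dc):min(w, w - dc)
      out[rd, cd] <- out[rd, cd] | m[rs, cs]
    }
  }
  out
}

#' Simulate a multi-block acquisition study
#'
#' Emulates the study schedule: each tissue block is imaged
#' `frames_per_block` times with 0, 1, ..., `frames_per_block - 1` lesions
#' (lesions accumulate, as successive ablations extend the treated region).
#' Block-level biological variation is modeled as a random multiplicative
#' spectral tilt plus a block-specific sensitivity field and background
#' jitter shared by all frames of the block.
#'
#' @param config A [phantom_config()].
#' @param n_blocks Number of tissue blocks (19 in the emulated study).
#' @param frames_per_block Frames per block (4 in the emulated study).
#' @param seed Master seed (defaults to `config$seed`).
#' @return List of [pa_frame()] objects, length `n_blocks * frames_per_block`.
#' @export
make_study <- function(config, n_blocks, frames_per_block = 4,
                       seed = config$seed) {
  stopifnot(frames_per_block >= 1)
  tilts <- withr::with_seed(seed, stats::rnorm(n_blocks, sd = 0.04))
  mid <- mean(range(config$grid$values))
  halfspan <- max(diff(range(config$grid$values)) / 2, 1)
  frames <- vector("list", n_blocks * frames_per_block)
  idx <- 1L
  for (b in seq_len(n_blocks)) {
    tilt_fac <- 1 + tilts[b] * (config$grid$values - mid) / halfspan
    cfg_b <- config
    cfg_b$mu_abs_nonablated <- config$mu_abs_nonablated * tilt_fac
    cfg_b$mu_abs_ablated <- config$mu_abs_ablated * tilt_fac
    block_seed <- (seed + 7919L * b) %% .Machine$integer.max
    for (j in seq_len(frames_per_block) - 1L) {
      scene <- build_scene(cfg_b, n_lesions = j, seed = block_seed)
      frame_seed <- (block_seed + 131L * j + 1L) %% .Machine$integer.max
      cube <- render_mwpa(scene, cfg_b, seed = frame_seed)
      us <- render_us(scene, cfg_b, seed = block_seed)
      mask <- make_mask(scene, cfg_b)
      frames[[idx]] <- pa_frame(cube, us, mask,
                                block_id = sprintf("block%02d", b),
                                n_lesions = j)
      idx <- idx + 1L
    }
  }
  frames
}
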