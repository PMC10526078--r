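# Shared fixtures, memoized so expensive phantom builds run once per suite.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 5-wavelength grid for cheap cube tests
tiny_grid <- function() make_grid(690, 710, 5)

# desk-scale scene sampled very coarsely: 24 x 32 px over the full 38-mm
# view; lesions are ~4 x 3 px
tiny_config <- function(...) {
  args <- list(grid = tiny_grid(), height_px = 24, width_px = 32,
               pixel_pitch_um = 73.92 * 16, boundary_band_px = 1,
               sidelobe = FALSE, seed = 7L)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_config, args)
}

# all imaging factors switched off: render equals the absorption field
clean_config <- function(grid = tiny_grid(), ...) {
  tiny_config(grid = grid, sensitivity_amp = 0, grueneisen = 1,
              mu_eff = rep(0, length(grid$values)),
              fluence = fluence_spectrum(grid, rep(1, length(grid$values))),
              noise_sigma = 0, spectrum_jitter_cv = 0, ...)
}

# 5 channels straddling the 757-nm feature and 775-nm ablation bump, where
# the two tissue classes actually differ after normalization
contrast_grid <- function() make_grid(730, 790, 15)

# small but statistically meaningful study on the full 53-wavelength grid
spectral_config <- function(...) {
  reduced_phantom_config(height_px = 48, width_px = 64,
                         pixel_pitch_um = 73.92 * 8,
                         boundary_band_px = 2, seed = 7L, ...)
}

tiny_study <- function() {
  memo("tiny_study", {
    cfg <- spectral_config()
    preprocess_frames(make_study(cfg, 3, 4, seed = 7L), cfg$fluence)
  })
}

# hand-built frame with prescribed mask codes and constant spectra
fake_frame <- function(h = 6, w = 8, grid = tiny_grid(), block_id = "b1",
                       mask_codes = NULL, state = "max_normalized",
                       n_lesions = 0) {
  nl <- length(grid$values)
  v <- array(stats::runif(h * w * nl), dim = c(h, w, nl))
  if (state == "max_normalized") {
    mx <- apply(v, c(1, 2), max)
    v <- sweep(v, c(1, 2), mx, "/")
  }
  if (is.null(mask_codes)) mask_codes <- matrix(MASK_NON_ABLATED, h, w)
  pa_frame(mwpa_cube(v, grid, state = state),
           us_image(matrix(0.5, h, w)), label_mask(mask_codes),
           block_id, n_lesions)
}

# separable two-class spectra dataset (for classifier unit tests)
gaussian_dataset <- function(n_per_class = 500, p = 5, shift = 3,
                             seed = 42L) {
  withr::with_seed(seed, {
    X0 <- matrix(stats::rnorm(n_per_class * p), ncol = p)
    X1 <- matrix(stats::rnorm(n_per_class * p), ncol = p)
    X1[, 1] <- X1[, 1] + shift
  })
  structure(
    list(features = rbind(X0, X1),
         labels = rep(c(0L, 1L), each = n_per_class),
         block_ids = rep("b", 2 * n_per_class),
         frame_ids = rep(1L, 2 * n_per_class),
         grid = grid_from_values(seq(700, by = 10, length.out = p))),
    class = "pixel_dataset")
}
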