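test_that("build_scene lays out the requested lesions", {
  cfg <- tiny_config()
  expect_equal(sum(build_scene(cfg, 0)$tissue_map >= 2), 0)

  sc3 <- build_scene(cfg, 3)
  expect_equal(count_lesions(make_mask(sc3, cfg)), 3)
  # lesion centers straddle the centerline: one left, one central, one right
  mid <- cfg$width_px / 2
  for (k in 1:3) {
    cols <- which(apply(sc3$tissue_map == 1 + k, 2, any))
    offset_px <- mean(cols) - mid
    expected <- cfg$lesion_offsets_mm[k] / (cfg$pixel_pitch_um * 1e-3)
    expect_equal(offset_px, expected, tolerance = 1.5)
  }
})

test_that("overlapping lesions merge into fewer connected components", {
  cfg <- tiny_config(lesion_offsets_mm = c(-1.5, 0, 1.5))
  sc <- build_scene(cfg, 3)
  expect_lt(count_lesions(make_mask(sc, cfg)), 3)
  expect_identical(sc$n_lesions, 3L)
})

test_that("lesions outside the frame are rejected", {
  cfg <- tiny_config(lesion_offsets_mm = c(-30, 0, 5))
  expect_error(build_scene(cfg, 1), "beyond the frame")
})

test_that("unit-factor render reproduces the absorption field exactly", {
  cfg <- clean_config()
  sc <- build_scene(cfg, 2)
  cube <- render_mwpa(sc, cfg)
  expect_identical(cube$state, "raw")
  expect_equal(cube$intensities, sc$mu_abs_field, tolerance = 0)
})

test_that("render is linear in the fluence, channel by channel", {
  cfg <- clean_config()
  sc <- build_scene(cfg, 1)
  f2 <- c(2, 1, 1, 1, 1)
  cfg2 <- cfg
  cfg2$fluence <- fluence_spectrum(cfg$grid, f2)
  a <- render_mwpa(sc, cfg)$intensities
  b <- render_mwpa(sc, cfg2)$intensities
  expect_equal(b[, , 1], 2 * a[, , 1])
  expect_equal(b[, , -1], a[, , -1])
})

test_that("channel-wise division by F(lambda) equals a unit-fluence render", {
  cfg <- tiny_config(noise_sigma = 0)
  sc <- build_scene(cfg, 2)
  with_f <- render_mwpa(sc, cfg)$intensities
  cfg1 <- cfg
  cfg1$fluence <- fluence_spectrum(cfg$grid,
                                   rep(1, length(cfg$grid$values)))
  unit_f <- render_mwpa(sc, cfg1)$intensities
  expect_equal(sweep(with_f, 3, cfg$fluence$energy_mJ, "/"), unit_f,
               tolerance = 1e-12)
})

test_that("noise-free intensity strictly decreases with depth", {
  cfg <- clean_config(mu_eff = rep(1.5, 5))
  sc <- build_scene(cfg, 0)
  v <- render_mwpa(sc, cfg)$intensities
  tissue_rows <- which(apply(sc$tissue_map == 1, 1, all))
  col <- v[tissue_rows, 3, 1]
  expect_true(all(diff(col) < 0))
})

test_that("mask partitions the frame; boundary band is wider axially", {
  cfg <- tiny_config(boundary_band_px = 2)
  sc <- build_scene(cfg, 1)
  mask <- unclass(make_mask(sc, cfg))
  expect_true(all(mask %in% 0:2))

  lesion <- sc$tissue_map >= 2
  labeled_or_les <- mask != MASK_UNLABELED | lesion
  # the band widens the lesion's bounding box by 2*band axially, band
  # laterally
  band_zone <- mask == MASK_UNLABELED & sc$tissue_map == 1
  les_rows <- range(which(apply(lesion, 1, any)))
  les_cols <- range(which(apply(lesion, 2, any)))
  zone_rows <- range(which(apply(band_zone | lesion, 1, any)))
  zone_cols <- range(which(apply(band_zone | lesion, 2, any)))
  expect_equal(zone_rows, les_rows + c(-4, 4))
  expect_equal(zone_cols, les_cols + c(-2, 2))

  # band 0: tissue is fully labeled
  cfg0 <- tiny_config(boundary_band_px = 0)
  sc0 <- build_scene(cfg0, 2)
  m0 <- unclass(make_mask(sc0, cfg0))
  expect_true(all(m0[sc0$tissue_map >= 1] != MASK_UNLABELED))
  # and no-lesion masks contain no ablated pixels
  expect_equal(sum(unclass(make_mask(build_scene(cfg0, 0), cfg0)) ==
                     MASK_ABLATED), 0)
  # water is never labeled
  expect_true(all(m0[sc0$tissue_map == 0] == MASK_UNLABELED))
})

test_that("confuser specks are background-labeled but carry the ablated spectrum", {
  cfg <- tiny_config(sidelobe = TRUE, speck_rate = 0.03,
                     spectrum_jitter_cv = 0)
  sc <- build_scene(cfg, 1)
  expect_gt(sum(sc$speck_map), 0)
  mask <- unclass(make_mask(sc, cfg))
  in_clear <- sc$speck_map & mask != MASK_UNLABELED
  expect_true(all(mask[in_clear] == MASK_NON_ABLATED))
  px <- which(sc$speck_map, arr.ind = TRUE)[1, ]
  expect_equal(sc$mu_abs_field[px[1], px[2], ], cfg$mu_abs_ablated,
               ignore_attr = TRUE)
})

test_that("ultrasound backdrop: tissue brighter than water, deterministic", {
  cfg <- tiny_config()
  sc <- build_scene(cfg, 1)
  us1 <- render_us(sc, cfg)
  us2 <- render_us(sc, cfg)
  expect_identical(us1$intensities, us2$intensities)
  expect_equal(dim(us1$intensities), c(cfg$height_px, cfg$width_px))
  expect_lt(mean(us1$intensities[sc$tissue_map == 0]),
            mean(us1$intensities[sc$tissue_map >= 1]))
})

test_that("make_study follows the acquisition schedule deterministically", {
  cfg <- tiny_config()
  st <- make_study(cfg, 19, 4, seed = 3)
  expect_length(st, 76)

  one <- make_study(cfg, 1, 4, seed = 3)
  expect_equal(vapply(one, function(f) f$n_lesions, 0L), 0:3)
  # lesions accumulate: masks of later frames contain earlier lesions
  abl <- vapply(one, function(f) sum(unclass(f$mask) == MASK_ABLATED), 0)
  expect_true(all(diff(abl) > 0))

  a <- make_study(cfg, 2, 1, seed = 9)
  b <- make_study(cfg, 2, 1, seed = 9)
  expect_identical(a, b)

  # block-level fields are shared within a block: background sensitivity
  # identical across the 0- and 1-lesion frames
  s0 <- make_study(cfg, 1, 2, seed = 5)
  expect_equal(s0[[1]]$cube$grid$values, cfg$grid$values)
  expect_identical(s0[[1]]$block_id, s0[[2]]$block_id)
})

test_that("generated spectra peak their class ratio inside 720-790 nm", {
  frames <- tiny_study()
  ds <- extract_pixels(frames)
  ms <- mean_spectra(ds)
  peak <- ms$wavelength_nm[which.max(ms$ratio)]
  expect_gte(peak, 720)
  expect_lte(peak, 790)
})

test_that("phantom config validates its physics", {
  g <- make_grid(690, 950, 5)
  expect_error(
    phantom_config(grid = g, mu_abs_ablated = rev(mu_abs_ablated_default(g))),
    "720-790")
  expect_error(tiny_config(noise_sigma = -1), "noise_sigma")
  expect_error(
    tiny_config(fluence = fluence_spectrum(make_grid(690, 700, 5),
                                           rep(1, 3))),
    "grid mismatch")
})
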