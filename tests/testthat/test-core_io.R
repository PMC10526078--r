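test_that("make_grid enumerates wavelengths and validates the range", {
  g <- make_grid(690, 950, 5)
  expect_length(g$values, 53)
  expect_equal(g$values[5], 710)  # 5th channel sits at 690 + 4 * 5
  expect_identical(make_grid(690, 690, 5)$values, 690)
  expect_equal(make_grid(690, 700, 5)$values, c(690, 695, 700))
  expect_true(all(diff(g$values) > 0))

  expect_error(make_grid(690, 948, 5), "remainder")
  expect_error(make_grid(690, 950, -5), "step")
  expect_error(make_grid(950, 690, 5), ">=")
})

test_that("grid_from_values accepts irregular subsets, rejects disorder", {
  g <- grid_from_values(c(720, 775, 780))
  expect_true(is.na(g$step_nm))
  expect_error(grid_from_values(c(780, 775)), "increasing")
  expect_error(grid_from_values(c(700, 700)), "increasing")
})

test_that("acquisition rate arithmetic matches the system timing", {
  expect_equal(acquisition_rate(1), 10)
  expect_equal(acquisition_rate(2), 5)
  expect_equal(acquisition_rate(53), 20 / 106)
})

test_that("cube HDF5 round trip is bit-exact and self-describing", {
  g <- tiny_grid()
  v <- array(runif(6 * 8 * 5), dim = c(6, 8, 5))
  cube <- mwpa_cube(v, g, pixel_pitch_um = 50, state = "raw")
  path <- withr::local_tempfile(fileext = ".h5")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$intensities, v)
  expect_equal(back$grid$values, g$values)
  expect_equal(back$pixel_pitch_um, 50)
  expect_identical(back$state, "raw")
})

test_that("cube files with missing or inconsistent datasets are rejected", {
  path <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path)
  rhdf5::h5write(array(1, dim = c(2, 2, 3)), path, "intensities")
  rhdf5::h5closeAll()
  expect_error(read_cube(path), "missing dataset")

  path2 <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(path2)
  rhdf5::h5write(array(1, dim = c(2, 2, 3)), path2, "intensities")
  rhdf5::h5write(c(690, 695), path2, "wavelengths_nm")
  rhdf5::h5write(73.92, path2, "pixel_pitch_um")
  rhdf5::h5write("raw", path2, "state")
  rhdf5::h5closeAll()
  expect_error(read_cube(path2), "3 channel page\\(s\\) but 2 wavelengths")

  expect_error(read_cube(withr::local_tempfile(fileext = ".h5")),
               "no such file")
})

test_that("raw cubes reject negative or non-finite intensities", {
  g <- tiny_grid()
  v <- array(1, dim = c(2, 2, 5))
  v[1, 1, 1] <- -0.5
  expect_error(mwpa_cube(v, g, state = "raw"), "negative")
  v[1, 1, 1] <- NA
  expect_error(mwpa_cube(v, g), "finite")
  expect_error(mwpa_cube(array(1, dim = c(2, 2, 4)), g), "channels")
})

test_that("mask PNG round trip preserves codes; foreign codes rejected", {
  codes <- matrix(sample(0:2, 24, replace = TRUE), 4, 6)
  mask <- label_mask(codes)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(mask, path)
  expect_identical(unclass(read_mask(path)), unclass(mask))

  # all-unlabeled mask is valid
  zero <- label_mask(matrix(0L, 3, 3))
  write_mask(zero, path)
  expect_true(all(unclass(read_mask(path)) == MASK_UNLABELED))

  # a file carrying byte value 3 fails validation
  png::writePNG(matrix(3 / 255, 2, 2), path)
  expect_error(read_mask(path), "outside")
  expect_error(label_mask(matrix(c(0L, 1L, 2L, 3L), 2, 2)), "codes")
})

test_that("fluence CSV round trip and validation", {
  fl <- default_fluence(make_grid(690, 950, 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluence(fl, path)
  back <- read_fluence(path)
  expect_equal(back$energy_mJ, fl$energy_mJ, tolerance = 1e-8)
  expect_equal(back$grid$values, fl$grid$values)
  expect_error(fluence_spectrum(tiny_grid(), c(1, 2, 3, 0, 5)), "positive")
  expect_error(fluence_spectrum(tiny_grid(), c(1, 2)), "length")
})

test_that("image view extent matches the acquisition geometry", {
  expect_equal(view_extent_cm(512, 73.92), 3.78, tolerance = 0.01 / 3.78)
  expect_equal(view_extent_cm(339, 73.92), 2.5, tolerance = 0.01)
})

test_that("frame members must share H x W", {
  g <- tiny_grid()
  cube <- mwpa_cube(array(1, dim = c(4, 6, 5)), g)
  expect_error(pa_frame(cube, us_image(matrix(0, 3, 6)),
                        label_mask(matrix(0L, 4, 6)), "b", 0), "US")
  expect_error(pa_frame(cube, us_image(matrix(0, 4, 6)),
                        label_mask(matrix(0L, 4, 5)), "b", 0), "mask")
})
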