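test_that("in-package QDA agrees with the MASS reference on Gaussian data", {
  ds <- gaussian_dataset(800, p = 5, shift = 5)
  fit <- palseg:::qda_fit(ds$features, ds$labels)
  ref <- MASS::qda(ds$features, grouping = factor(ds$labels))
  test <- gaussian_dataset(500, p = 5, shift = 5, seed = 77)
  mine <- palseg:::qda_predict(fit, test$features)
  theirs <- as.integer(as.character(stats::predict(ref,
                                                   test$features)$class))
  expect_gt(mean(mine == theirs), 0.995)
  # well-separated classes: training error < 1%
  expect_lt(mean(palseg:::qda_predict(fit, ds$features) != ds$labels), 0.01)
})

test_that("QDA falls back to a ridge on singular covariances", {
  X <- cbind(rep(c(0, 1), each = 50), rep(c(0, 1), each = 50))  # rank 1
  X <- X + cbind(stats::rnorm(100, sd = 1e-12), 0)
  y <- rep(c(0L, 1L), each = 50)
  expect_message(fit <- palseg:::qda_fit(X, y), "ridge")
  expect_equal(palseg:::qda_predict(fit, X), y)
})

test_that("train_classic applies the tuned defaults and rejects degenerate input", {
  ds <- gaussian_dataset(200)
  spec <- model_spec("nn")
  expect_equal(spec$hyperparams$hidden_nodes, 53)
  expect_equal(model_spec("svm")$hyperparams$C, 16)
  expect_equal(model_spec("rf")$hyperparams$n_trees, 50)
  expect_equal(model_spec("rf")$hyperparams$min_samples_leaf, 1000)
  expect_error(model_spec("qda", C = 2), "unknown hyperparameter")

  one_class <- ds
  one_class$labels <- rep(0L, length(ds$labels))
  expect_error(train_classic(spec, one_class), "single class")

  # the neural network has exactly one hidden layer
  nn <- train_classic(model_spec("nn", epochs = 20), ds, seed = 1)
  expect_named(nn$fit$params, c("W1", "b1", "W2", "b2"))
  expect_equal(dim(nn$fit$params$W1), c(5, 53))
  expect_equal(dim(nn$fit$params$W2), c(53, 2))
})

test_that("all four families separate easy Gaussian classes", {
  ds <- gaussian_dataset(600, shift = 4)
  test <- gaussian_dataset(300, shift = 4, seed = 99)
  for (fam in c("qda", "nn", "svm", "rf")) {
    spec <- if (fam == "rf") model_spec(fam, min_samples_leaf = 50)
            else model_spec(fam)
    m <- train_classic(spec, ds, seed = 1)
    acc <- mean(predict_pixels(m, test$features) == test$labels)
    expect_gt(acc, 0.95)
  }
})

test_that("training is deterministic under a fixed seed", {
  ds <- gaussian_dataset(300)
  test <- gaussian_dataset(100, seed = 5)
  for (fam in c("nn", "svm", "rf")) {
    spec <- if (fam == "rf") model_spec(fam, min_samples_leaf = 30)
            else if (fam == "nn") model_spec(fam, epochs = 15)
            else model_spec(fam)
    a <- predict_pixels(train_classic(spec, ds, seed = 4), test$features)
    b <- predict_pixels(train_classic(spec, ds, seed = 4), test$features)
    expect_identical(a, b)
  }
})

test_that("larger leaf-size floors give strictly shallower forests", {
  ds <- gaussian_dataset(3000, shift = 2)
  deep <- palseg:::rf_fit(ds$features, ds$labels, n_trees = 10,
                 min_samples_leaf = 100, seed = 1)
  shallow <- palseg:::rf_fit(ds$features, ds$labels, n_trees = 10,
                    min_samples_leaf = 1000, seed = 1)
  expect_lt(max(shallow$max_depths), max(deep$max_depths))
})

test_that("segment_frame is a pixel-independent map of the right shape", {
  cfg <- tiny_config()
  st <- preprocess_frames(make_study(cfg, 1, 4, seed = 3), cfg$fluence)
  ds <- balance_pixels(extract_pixels(st), seed = 1)
  m <- train_classic(model_spec("qda"), ds, seed = 1)
  fr <- st[[4]]
  res <- segment_frame(m, fr)
  expect_equal(dim(res$decision), dim(unclass(fr$mask)))
  expect_equal(dim(res$scores), c(cfg$height_px, cfg$width_px, 2))

  # permuting two pixels permutes the two outputs
  fr2 <- fr
  p1 <- c(3, 4); p2 <- c(10, 20)
  fr2$cube$intensities[p1[1], p1[2], ] <- fr$cube$intensities[p2[1], p2[2], ]
  fr2$cube$intensities[p2[1], p2[2], ] <- fr$cube$intensities[p1[1], p1[2], ]
  res2 <- segment_frame(m, fr2)
  expect_equal(res2$decision[p1[1], p1[2]], res$decision[p2[1], p2[2]])
  expect_equal(res2$decision[p2[1], p2[2]], res$decision[p1[1], p1[2]])
  untouched <- res$decision
  untouched[rbind(p1, p2)] <- res2$decision[rbind(p1, p2)]
  expect_equal(res2$decision, untouched)

  # wavelength mismatch is rejected
  fr5 <- subset_frame(fr, c(690, 695))
  expect_error(segment_frame(m, fr5), "does not match")
  raw <- fr; raw$cube$state <- "raw"
  expect_error(segment_frame(m, raw), "preprocessed")
})

test_that("a lesion-free easy frame draws almost no false positives", {
  cfg <- clean_config(grid = contrast_grid(), spectrum_jitter_cv = 0.02,
                      noise_sigma = 0.005)
  st <- preprocess_frames(make_study(cfg, 1, 4, seed = 5), cfg$fluence)
  ds <- balance_pixels(extract_pixels(st), seed = 1)
  m <- train_classic(model_spec("qda"), ds, seed = 1)
  fr0 <- st[[1]]  # no lesions
  res <- segment_frame(m, fr0)
  labeled <- unclass(fr0$mask) != MASK_UNLABELED
  expect_lt(mean(res$decision[labeled] == 1), 0.01)
})

test_that("tuning_curve sweeps a parameter on a block-disjoint split", {
  st <- tiny_study()
  sp <- split_blocks(st, 2, 1, seed = 1)
  tc <- tuning_curve("rf", "min_samples_leaf", c(5000), sp$train, sp$test,
                     seed = 1)
  expect_equal(nrow(tc), 1)
  expect_true(all(c("value", "f1", "max_depth") %in% names(tc)))
  expect_error(tuning_curve("rf", "min_samples_leaf", c(100), sp$train,
                            sp$train, seed = 1), "share block")

  # growing the leaf floor from 100 to 5000 shrinks depth and cannot help F1
  tc2 <- tuning_curve("rf", "min_samples_leaf", c(100, 5000), sp$train,
                      sp$test, seed = 1)
  expect_lt(tc2$max_depth[2], tc2$max_depth[1])
  expect_lte(tc2$f1[2], tc2$f1[1] + 0.02)
})
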