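tiny_cnn_frame <- function(h = 16, w = 16, L = 3, seed = 2,
                           codes = NULL) {
  withr::with_seed(seed, {
    v <- array(runif(h * w * L), dim = c(h, w, L))
  })
  if (is.null(codes)) codes <- matrix(MASK_NON_ABLATED, h, w)
  pa_frame(mwpa_cube(v, grid_from_values(seq(700, by = 10,
                                             length.out = L)),
                     state = "max_normalized"),
           us_image(matrix(0, h, w)), label_mask(codes), "b1", 0)
}

test_that("architecture counts and shape contract", {
  expect_equal(cnn_pooled_dims(339, 512), c(42, 64))
  expect_equal(cnn_pooled_dims(96, 128), c(12, 16))

  net <- cnn_build(cnn_spec(53), seed = 1)
  # layer 1: 3 x 3 x 53 kernels, 53 of them, plus biases
  expect_equal(length(net$weights$W1) + length(net$weights$b1),
               3 * 3 * 53 * 53 + 53)
  expect_equal(dim(net$weights$W5), c(53, 2))

  net3 <- cnn_build(cnn_spec(3), seed = 1)
  fr <- tiny_cnn_frame(17, 23, 3)
  res <- cnn_segment(net3, fr)
  expect_equal(dim(res$scores), c(17, 23, 2))
  expect_equal(dim(res$decision), c(17, 23))

  fr64 <- tiny_cnn_frame(64, 64, 5)
  net5 <- cnn_build(cnn_spec(5), seed = 1)
  expect_equal(dim(cnn_segment(net5, fr64)$scores), c(64, 64, 2))

  expect_error(cnn_segment(net3, tiny_cnn_frame(7, 32, 3)), "8 x 8")
  expect_error(cnn_segment(net5, fr), "channels")
})

test_that("weighted cross-entropy matches the hand-computed toy case", {
  # mask [ablated, non-ablated; unlabeled, non-ablated], uniform scores,
  # w_ablated = 3 -> (3 + 1 + 0 + 1) * ln 2 / (3 + 1 + 0 + 1) = ln 2
  scores <- array(0.5, dim = c(2, 2, 2))
  mask <- label_mask(matrix(c(2L, 0L, 1L, 1L), 2, 2))
  w <- list(w_ablated = 3)
  expect_equal(cnn_loss(scores, mask, w), log(2))

  # all-unlabeled mask: zero loss
  expect_equal(cnn_loss(scores, label_mask(matrix(0L, 2, 2)), w), 0)

  # confident correct prediction drives the loss to zero
  sc <- array(0, dim = c(2, 2, 2))
  sc[, , 2] <- 20 * (unclass(mask) == 2)
  sc[, , 1] <- 20 * (unclass(mask) == 1)
  expect_lt(cnn_loss(sc, mask, w), 1e-6)
})

test_that("R loss and compiled training loss agree", {
  fr <- tiny_cnn_frame(16, 24, 3,
                       codes = matrix(sample(0:2, 16 * 24, TRUE), 16, 24))
  net <- cnn_build(cnn_spec(3), seed = 3)
  res <- cnn_gradients(net, fr, w_ablated = 4)
  scores <- cnn_segment(net, fr)$scores
  expect_equal(res$loss, cnn_loss(scores, fr$mask, list(w_ablated = 4)),
               tolerance = 1e-8)
})

test_that("analytic gradients match central differences", {
  fr <- tiny_cnn_frame(12, 16, 3,
                       codes = matrix(sample(0:2, 12 * 16, TRUE), 12, 16))
  net <- cnn_build(cnn_spec(3), seed = 2)
  res <- cnn_gradients(net, fr, w_ablated = 3)
  # forward pass runs in single precision: central differences carry
  # O(1e-3) relative noise, so compare loosely but meaningfully
  eps <- 1e-2
  for (nm in c("W1", "W3", "W5", "b2", "b5")) {
    n <- length(net$weights[[nm]])
    for (i in c(1L, n %/% 2 + 1L, n)) {
      up <- net; up$weights[[nm]][i] <- up$weights[[nm]][i] + eps
      dn <- net; dn$weights[[nm]][i] <- dn$weights[[nm]][i] - eps
      numeric <- (cnn_gradients(up, fr, 3)$loss -
                    cnn_gradients(dn, fr, 3)$loss) / (2 * eps)
      expect_equal(res$grads[[nm]][i], numeric, tolerance = 0.02)
    }
  }
})

test_that("unlabeled pixels contribute exactly zero loss and gradient", {
  fr <- tiny_cnn_frame(16, 16, 3, codes = matrix(0L, 16, 16))
  net <- cnn_build(cnn_spec(3), seed = 1)
  res <- cnn_gradients(net, fr, w_ablated = 10)
  expect_equal(res$loss, 0)
  expect_equal(res$weight_sum, 0)
  for (g in res$grads) expect_true(all(g == 0))
})

test_that("score ties resolve to non-ablated", {
  net <- cnn_build(cnn_spec(3), seed = 1)
  # zero weights give identical (zero) score channels everywhere
  for (nm in names(net$weights)) net$weights[[nm]][] <- 0
  res <- cnn_segment(net, tiny_cnn_frame(16, 16, 3))
  expect_equal(res$scores[, , 1], res$scores[, , 2])
  expect_true(all(res$decision == 0L))
})

test_that("training is deterministic and reduces the loss on easy data", {
  cfg <- clean_config(boundary_band_px = 1)
  st <- preprocess_frames(make_study(cfg, 1, 4, seed = 4), cfg$fluence)
  ccfg <- cnn_train_config(epochs = 8, lr = 1e-3, batch_size = 2, seed = 9)
  a <- cnn_fit(cnn_build(cnn_spec(5), seed = 9), st, ccfg)
  b <- cnn_fit(cnn_build(cnn_spec(5), seed = 9), st, ccfg)
  expect_identical(a$weights, b$weights)
  expect_lt(utils::tail(a$loss_trace, 1), a$loss_trace[1])

  mixed <- c(st, list(tiny_cnn_frame(16, 16, 3)))
  expect_error(cnn_fit(cnn_build(cnn_spec(5), seed = 1), mixed,
                       ccfg), "channels")
})

test_that("the network can overfit a single easy frame", {
  cfg <- clean_config(boundary_band_px = 1)
  st <- preprocess_frames(make_study(cfg, 1, 4, seed = 8), cfg$fluence)
  fr <- st[[4]]  # 3 lesions
  net <- cnn_fit(cnn_build(cnn_spec(5), seed = 3), list(fr),
                 cnn_train_config(epochs = 60, lr = 1e-3, batch_size = 1,
                                  seed = 3))
  f1 <- seg_metrics(confusion(cnn_segment(net, fr), fr$mask))$f1
  expect_gt(f1, 0.9)
})
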