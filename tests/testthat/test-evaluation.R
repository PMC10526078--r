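test_that("confusion counts match a brute-force tally, unlabeled excluded", {
  # forced 3-pixel example
  mask <- label_mask(matrix(c(2L, 1L, 0L), 3, 1))
  pred <- matrix(1L, 3, 1)
  cf <- confusion(pred, mask)
  expect_equal(unlist(cf[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 1, TN = 0, FN = 0))

  withr::with_seed(4, {
    for (trial in 1:20) {
      codes <- matrix(sample(0:2, 400, TRUE), 20, 20)
      pred <- matrix(sample(0:1, 400, TRUE), 20, 20)
      cf <- confusion(pred, label_mask(codes))
      tp <- tn <- fp <- fn <- 0
      for (i in 1:400) {
        if (codes[i] == 0) next
        truth <- codes[i] == 2
        p <- pred[i] == 1
        if (truth && p) tp <- tp + 1
        else if (!truth && !p) tn <- tn + 1
        else if (!truth && p) fp <- fp + 1
        else fn <- fn + 1
      }
      expect_equal(unlist(cf), c(TP = tp, TN = tn, FP = fp, FN = fn))
      expect_equal(cf$TP + cf$TN + cf$FP + cf$FN, sum(codes != 0))
    }
  })

  expect_equal(unlist(confusion(matrix(1L, 2, 2),
                                label_mask(matrix(0L, 2, 2)))),
               c(TP = 0, TN = 0, FP = 0, FN = 0))
  expect_error(confusion(matrix(1L, 2, 3), label_mask(matrix(0L, 2, 2))),
               "dimensions")
})

test_that("metrics implement the recall/precision/F1 formulas", {
  m <- seg_metrics(structure(list(TP = 9, TN = 0, FP = 1, FN = 1),
                             class = "confusion"))
  expect_equal(m$recall, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$f1, 0.9)

  m2 <- seg_metrics(structure(list(TP = 3, TN = 5, FP = 1, FN = 2),
                              class = "confusion"))
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$f1, 2 * 0.6 * 0.75 / 1.35)
  expect_equal(round(m2$f1, 4), 0.6667)
  # f1 lies between recall and precision
  expect_gte(m2$f1, min(m2$recall, m2$precision))
  expect_lte(m2$f1, max(m2$recall, m2$precision))

  # degenerate cases go to zero
  z <- seg_metrics(structure(list(TP = 0, TN = 4, FP = 2, FN = 3),
                             class = "confusion"))
  expect_equal(z$f1, 0)
  expect_equal(seg_metrics(structure(list(TP = 0, TN = 4, FP = 0, FN = 0),
                                     class = "confusion"))$f1, 0)
})

test_that("swapping FP and FN swaps recall and precision", {
  withr::with_seed(8, {
    for (i in 1:10) {
      cf <- as.list(stats::setNames(sample(0:30, 4, TRUE),
                                    c("TP", "TN", "FP", "FN")))
      sw <- cf; sw$FP <- cf$FN; sw$FN <- cf$FP
      a <- seg_metrics(structure(cf, class = "confusion"))
      b <- seg_metrics(structure(sw, class = "confusion"))
      expect_equal(a$recall, b$precision)
      expect_equal(a$f1, b$f1)
    }
  })
})

test_that("f1 equals one exactly when the prediction is perfect", {
  codes <- matrix(c(2L, 2L, 1L, 0L), 2, 2)
  perfect <- matrix(c(1L, 1L, 0L, 1L), 2, 2)  # unlabeled pixel irrelevant
  m <- seg_metrics(confusion(perfect, label_mask(codes)))
  expect_equal(m$f1, 1)
})

test_that("score_algorithm averages per-frame F1, skipping lesion-free frames", {
  mk <- function(codes, pred) list(result = pred, mask = label_mask(codes))
  full <- matrix(c(2L, 1L, 1L, 1L), 2, 2)
  # frame A: perfect (F1 = 1); frame B: recall 1, precision 0.5
  a <- mk(full, matrix(c(1L, 0L, 0L, 0L), 2, 2))
  b <- mk(full, matrix(c(1L, 1L, 0L, 0L), 2, 2))
  f1b <- 2 * 1 * 0.5 / 1.5
  expect_equal(score_algorithm(list(a, b)), (1 + f1b) / 2)
  expect_equal(score_algorithm(list(b)), f1b)

  none <- mk(matrix(1L, 2, 2), matrix(0L, 2, 2))
  expect_equal(score_algorithm(list(a, none)), 1)
  expect_error(score_algorithm(list(none)), "no test frame")
})

test_that("experiment_grid produces the model x wavelength table", {
  st <- tiny_study()
  sp <- split_blocks(st, 2, 1, seed = 3)
  ds <- balance_pixels(extract_pixels(sp$train), seed = 1)
  trace <- sequential_select(ds, seed = 1, max_k = 3)
  grid <- experiment_grid(sp$train, sp$test, trace = trace,
                          wavelength_counts = c(53, 3, 2),
                          families = c("qda", "rf"), seed = 1)
  expect_equal(dim(grid$f1), c(3, 2))
  expect_equal(rownames(grid$f1), c("53", "3", "2"))
  expect_equal(colnames(grid$f1), c("QDA", "RF"))
  expect_true(all(grid$f1 >= 0 & grid$f1 <= 1))
  expect_equal(grid$decrease["from 53 to 3", ],
               grid$f1["53", ] - grid$f1["3", ])
  expect_equal(grid$decrease["from 3 to 2", ],
               grid$f1["3", ] - grid$f1["2", ])
  expect_error(
    experiment_grid(sp$train, sp$test, trace = NULL,
                    wavelength_counts = c(53, 2), families = "qda"),
    "selection trace")
})
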