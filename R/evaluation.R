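#' Confusion counts over labeled pixels
#'
#' Ablated is the positive class; unlabeled pixels are excluded from all
#' four counts.
#'
#' @param result A [segmentation_result()] (or 0/1 decision matrix).
#' @param mask A [label_mask()] of the same H x W.
#' @return A `confusion` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(result, mask) {
  decision <- if (inherits(result, "segmentation_result")) result$decision
              else result
  if (!all(dim(decision) == dim(mask))) {
    stop("prediction and mask dimensions differ")
  }
  codes <- unclass(mask)
  pos <- codes == MASK_ABLATED
  neg <- codes == MASK_NON_ABLATED
  pred <- decision == 1L
  structure(list(TP = sum(pos & pred), TN = sum(neg & !pred),
                 FP = sum(neg & pred), FN = sum(pos & !pred)),
            class = "confusion")
}

#' Recall, precision and F1 from confusion counts
#'
#' `recall = TP / (TP + FN)`, `precision = TP / (TP + FP)`,
#' `F1 = 2 * recall * precision / (recall + precision)`. Degenerate zero
#' denominators yield 0.
#'
#' @param conf A [confusion()] result.
#' @return A `seg_metrics` list with `recall`, `precision`, `f1`.
#' @export
seg_metrics <- function(conf) {
  recall <- if (conf$TP + conf$FN > 0) conf$TP / (conf$TP + conf$FN) else 0
  precision <- if (conf$TP + conf$FP > 0) conf$TP / (conf$TP + conf$FP) else 0
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  structure(list(recall = recall, precision = precision, f1 = f1),
            class = "seg_metrics")
}

#' Mean F1 of an algorithm over test frames
#'
#' Unweighted mean of per-frame F1 over the frames that contain at least
#' one ablated labeled pixel (per-frame F1 is undefined on lesion-free
#' frames, which are skipped).
#'
#' @param results List of `list(result = , mask = )` pairs, one per test
#'   frame.
#' @return Mean F1 in `[0, 1]`.
#' @export
score_algorithm <- function(results) {
  stopifnot(length(results) > 0)
  f1s <- vapply(results, function(r) {
    if (!any(unclass(r$mask) == MASK_ABLATED)) return(NA_real_)
    seg_metrics(confusion(r$result, r$mask))$f1
  }, 0)
  f1s <- f1s[!is.na(f1s)]
  if (length(f1s) == 0) stop("no test frame contains ablated labeled pixels")
  mean(f1s)
}

segment_with <- function(model, frame) {
  if (inherits(model, "cnn_model")) cnn_segment(model, frame)
  else segment_frame(model, frame)
}

#' Mean test F1 of a fitted model over frames
#'
#' @param model A `classic_model` or `cnn_model`.
#' @param frames Preprocessed test frames.
#' @return Mean F1 (see [score_algorithm()]).
#' @export
evaluate_model <- function(model, frames) {
  # lesion-free frames are skipped by score_algorithm anyway; don't spend
  # segmentation time on them
  has_abl <- vapply(frames,
                    function(fr) any(unclass(fr$mask) == MASK_ABLATED),
                    TRUE)
  if (!any(has_abl)) stop("no test frame contains ablated labeled pixels")
  score_algorithm(lapply(frames[has_abl], function(fr) {
    list(result = segment_with(model, fr), mask = fr$mask)
  }))
}

#' Model x wavelength-count F1 grid
#'
#' Trains every requested model family at every wavelength count (full grid
#' or the first k most-important wavelengths of the selection trace) and
#' reports the mean test F1, plus the consecutive-row decrease table.
#'
#' @param train,test Preprocessed frame lists (block-disjoint).
#' @param trace A [sequential_select()] trace providing the wavelength
#'   importance order (required when any count is below the full grid).
#' @param wavelength_counts Wavelength counts, e.g. `c(53, 5, 4, 3, 2)`.
#' @param families Model columns among `"qda"`, `"nn"`, `"svm"`, `"rf"`,
#'   `"cnn"`.
#' @param seed Training seed.
#' @param cnn_config A [cnn_train_config()] for the CNN column.
#' @param balance_seed Seed for the per-frame under-sampling.
#' @return An `experiment_grid` list with `f1` (counts x families matrix,
#'   values in 0--1), `decrease` (consecutive differences) and the inputs
#'   used.
#' @export
experiment_grid <- function(train, test, trace = NULL,
                            wavelength_counts = c(53, 5, 4, 3, 2),
                            families = c("qda", "nn", "svm", "rf", "cnn"),
                            seed = 1L, cnn_config = cnn_train_config(),
                            balance_seed = seed) {
  full <- length(train[[1]]$cube$grid$values)
  if (any(wavelength_counts > full)) stop("wavelength count exceeds grid")
  if (any(wavelength_counts < full) && is.null(trace)) {
    stop("a selection trace is required for reduced wavelength counts")
  }
  f1 <- matrix(NA_real_, length(wavelength_counts), length(families),
               dimnames = list(as.character(wavelength_counts),
                               toupper(families)))
  for (i in seq_along(wavelength_counts)) {
    k <- wavelength_counts[i]
    if (k == full) {
      tr_k <- train; te_k <- test
    } else {
      ranking <- if (length(trace$order) >= k) trace$order
                 else trace$extended_order
      if (length(ranking) < k) {
        stop("selection trace has fewer than ", k, " wavelengths")
      }
      wl <- ranking[seq_len(k)]
      tr_k <- lapply(train, subset_frame, wavelengths_nm = wl)
      te_k <- lapply(test, subset_frame, wavelengths_nm = wl)
    }
    dataset <- balance_pixels(extract_pixels(tr_k), seed = balance_seed)
    for (j in seq_along(families)) {
      fam <- families[j]
      model <- if (fam == "cnn") {
        cfg <- cnn_config
        cfg$seed <- as.integer(seed)
        net <- cnn_build(cnn_spec(k), seed = seed)
        cnn_fit(net, tr_k, cfg)
      } else {
        train_classic(model_spec(fam), dataset, seed = seed)
      }
      f1[i, j] <- evaluate_model(model, te_k)
    }
  }
  decrease <- if (nrow(f1) > 1) {
    d <- f1[-nrow(f1), , drop = FALSE] - f1[-1, , drop = FALSE]
    rownames(d) <- paste("from", wavelength_counts[-length(wavelength_counts)],
                         "to", wavelength_counts[-1])
    d
  } else NULL
  structure(list(f1 = f1, decrease = decrease,
                 wavelength_counts = wavelength_counts,
                 families = toupper(families), seed = seed),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("F1 score (%) by wavelength count:\n")
  print(round(100 * x$f1, 2))
  invisible(x)
}
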