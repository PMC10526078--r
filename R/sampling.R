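#' Extract labeled pixels as a spectral dataset
#'
#' One row per labeled (non-unlabeled) pixel of every frame; features are
#' the pixel's normalized spectrum. Frames must be preprocessed
#' (`max_normalized`) so features are comparable across frames.
#'
#' @param frames List of preprocessed [pa_frame()].
#' @return A `pixel_dataset`: list with `features` (N x Lambda matrix),
#'   `labels` (N, 1 = ablated, 0 = non-ablated), `block_ids`, `frame_ids`,
#'   `grid`.
#' @export
extract_pixels <- function(frames) {
  stopifnot(length(frames) > 0)
  feats <- vector("list", length(frames))
  labs <- vector("list", length(frames))
  blocks <- vector("list", length(frames))
  fids <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (fr$cube$state != "max_normalized") {
      stop("frame ", i, " is not preprocessed (state ", fr$cube$state, ")")
    }
    keep <- which(unclass(fr$mask) != MASK_UNLABELED)
    d <- dim(fr$cube$intensities)
    m <- matrix(fr$cube$intensities, d[1] * d[2], d[3])
    feats[[i]] <- m[keep, , drop = FALSE]
    labs[[i]] <- as.integer(unclass(fr$mask)[keep] == MASK_ABLATED)
    blocks[[i]] <- rep(fr$block_id, length(keep))
    fids[[i]] <- rep(i, length(keep))
  }
  structure(
    list(features = do.call(rbind, feats), labels = unlist(labs),
         block_ids = unlist(blocks), frame_ids = unlist(fids),
         grid = frames[[1]]$cube$grid),
    class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf(
    "<pixel_dataset> %d pixels (%d ablated), %d wavelengths, %d block(s)\n",
    length(x$labels), sum(x$labels), ncol(x$features),
    length(unique(x$block_ids))))
  invisible(x)
}

subset_dataset <- function(dataset, keep) {
  dataset$features <- dataset$features[keep, , drop = FALSE]
  dataset$labels <- dataset$labels[keep]
  dataset$block_ids <- dataset$block_ids[keep]
  dataset$frame_ids <- dataset$frame_ids[keep]
  dataset
}

#' Balance a pixel dataset by per-frame under-sampling
#'
#' For each frame containing ablated pixels, keeps all ablated rows and an
#' equal number of randomly chosen non-ablated rows (without replacement).
#' Frames without ablated pixels contribute nothing to the balanced set. If
#' a frame has fewer non-ablated than ablated pixels, all its non-ablated
#' rows are kept (no up-sampling).
#'
#' @param dataset A [extract_pixels()] result.
#' @param seed Random seed.
#' @return A balanced `pixel_dataset`.
#' @export
balance_pixels <- function(dataset, seed = 1L) {
  if (sum(dataset$labels) == 0) stop("dataset contains no ablated pixels")
  keep <- withr::with_seed(seed, {
    unlist(lapply(unique(dataset$frame_ids), function(fid) {
      rows <- which(dataset$frame_ids == fid)
      pos <- rows[dataset$labels[rows] == 1L]
      if (length(pos) == 0) return(integer(0))
      neg <- rows[dataset$labels[rows] == 0L]
      if (length(neg) > length(pos)) {
        neg <- sample(neg, length(pos))
      }
      c(pos, neg)
    }))
  })
  subset_dataset(dataset, sort(keep))
}

#' Split frames into train and test sets by tissue block
#'
#' All frames of a block land on the same side, preventing leakage of
#' block-level appearance between training and testing.
#'
#' @param frames List of [pa_frame()].
#' @param n_train,n_test Block counts; must sum to the number of distinct
#'   blocks.
#' @param seed Random seed for the block draw.
#' @return List with `train` and `test` frame lists, plus `train_blocks`
#'   and `test_blocks`.
#' @export
split_blocks <- function(frames, n_train, n_test, seed = 1L) {
  blocks <- unique(vapply(frames, function(f) as.character(f$block_id), ""))
  if (n_train + n_test != length(blocks)) {
    stop(sprintf("n_train + n_test = %d but there are %d distinct blocks",
                 n_train + n_test, length(blocks)))
  }
  train_blocks <- withr::with_seed(seed, sample(blocks, n_train))
  test_blocks <- setdiff(blocks, train_blocks)
  in_train <- vapply(frames, function(f) f$block_id %in% train_blocks, TRUE)
  list(train = frames[in_train], test = frames[!in_train],
       train_blocks = train_blocks, test_blocks = test_blocks)
}

#' Class weights for the weighted cross-entropy loss
#'
#' Non-ablated pixels weigh 1, unlabeled pixels 0, and ablated pixels the
#' global non-ablated:ablated labeled-pixel count ratio of the given frames,
#' compensating the heavy class imbalance.
#'
#' @param frames List of [pa_frame()].
#' @return A `class_weights` list: `w_ablated`, `w_nonablated` (1),
#'   `w_unlabeled` (0).
#' @export
class_weights <- function(frames) {
  n_abl <- sum(vapply(frames, function(f) sum(unclass(f$mask) == MASK_ABLATED),
                      0))
  n_non <- sum(vapply(frames,
                      function(f) sum(unclass(f$mask) == MASK_NON_ABLATED), 0))
  if (n_abl == 0) stop("no ablated pixels in the given frames")
  structure(list(w_ablated = n_non / n_abl, w_nonablated = 1,
                 w_unlabeled = 0),
            class = "class_weights")
}
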