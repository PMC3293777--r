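#' Extract a raw-pixel patch
#'
#' Returns the row-major flattening of the `N x N` pixel neighborhood
#' centered at `(y, x)` on slice `z`.  Patches are strictly 2D (no Z
#' context).  Borders are handled by mirror padding so every in-plane
#' location has a full patch.
#'
#' @param volume an [intensity_volume()].
#' @param z,y,x 1-based voxel indices.
#' @param N odd patch side in pixels.
#' @return Numeric vector of length `N^2`.
#' @export
extract_patch <- function(volume, z, y, x, N = 11L) {
  N <- as.integer(N)
  d <- dim(volume)
  if (N %% 2L == 0L) stop("N must be odd")
  if (N > 2L * min(d[2], d[3])) stop("N larger than twice the slice extent")
  h <- (N - 1L) %/% 2L
  ys <- mirror_index(y + (-h:h), d[2])
  xs <- mirror_index(x + (-h:h), d[3])
  m <- slice_of(volume, z)[ys, xs, drop = FALSE]
  as.vector(t(m))   # row-major: x fastest within each patch row
}

# Reflect 1-based indices at the borders (symmetric padding, edge included):
# ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1L) %% (2L * n)
  p <- ifelse(p < 0L, p + 2L * n, p)
  ifelse(p < n, p + 1L, 2L * n - p)
}

#' Sample labeled training patches
#'
#' Draws exactly `n_pos` positive-center and `n_neg` negative-center voxels
#' uniformly at random without replacement from the whole labeled volume and
#' extracts their patches.  Deterministic given `seed`.
#'
#' @param volume an [intensity_volume()].
#' @param labels the aligned [label_volume()].
#' @param n_pos,n_neg number of positive / negative examples.
#' @param N odd patch side in pixels.
#' @param seed RNG seed.
#' @return List of class `patch_training_set`: `x` (`n x N^2` matrix),
#'   `y` (0/1), `counts`, `patch_size`, `seed`.
#' @export
sample_training_patches <- function(volume, labels, n_pos = 689L, n_neg = 902L,
                                    N = 11L, seed = 1L) {
  check_aligned(volume, labels)
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) < n_pos) stop("not enough positive voxels (", length(pos),
                                " < ", n_pos, ")")
  if (length(neg) < n_neg) stop("not enough negative voxels")
  sel <- with_seed(seed, c(sample(pos, n_pos), sample(neg, n_neg)))
  d <- dim(volume)
  zyx <- arrayInd(sel, d)
  x <- matrix(0, length(sel), N * N)
  for (i in seq_along(sel)) {
    x[i, ] <- extract_patch(volume, zyx[i, 1], zyx[i, 2], zyx[i, 3], N)
  }
  structure(list(x = x, y = rep(c(1L, 0L), c(n_pos, n_neg)),
                 counts = c(n_pos = n_pos, n_neg = n_neg),
                 patch_size = as.integer(N), seed = as.integer(seed),
                 index = sel),
            class = "patch_training_set")
}

#' Train the patch classifier
#'
#' Fits a probability random forest on raw `N^2`-long gray-value vectors.
#' No normalization or feature engineering is applied to the patches.
#'
#' @param ts a `patch_training_set`.
#' @param rf_trees number of trees.
#' @param seed RNG seed.
#' @return A `patch_model` wrapping a [ranger::ranger()] forest; its
#'   `oob_auc` field holds the out-of-bag ROC AUC.
#' @export
train_patch_model <- function(ts, rf_trees = 100L, seed = 1L) {
  if (length(unique(ts$y)) < 2) stop("both classes must be present for training")
  df <- as.data.frame(ts$x)
  names(df) <- paste0("p", seq_len(ncol(ts$x)))
  df$y <- factor(ts$y, levels = c(0, 1))
  fit <- ranger::ranger(y ~ ., data = df, num.trees = rf_trees,
                        probability = TRUE, seed = as.integer(seed),
                        num.threads = 1L)
  oob <- fit$predictions[, "1"]
  ok <- is.finite(oob)
  structure(list(forest = fit, patch_size = ts$patch_size,
                 counts = ts$counts, seed = as.integer(seed),
                 rf_trees = as.integer(rf_trees),
                 oob_auc = score_auc(oob[ok], ts$y[ok])),
            class = "patch_model")
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("<patch_model> %dx%d raw patches, %d trees, %d+/%d-, OOB AUC %.3f\n",
              x$patch_size, x$patch_size, x$rf_trees,
              x$counts["n_pos"], x$counts["n_neg"], x$oob_auc))
  invisible(x)
}

#' Per-voxel mitochondria probability map
#'
#' Applies the patch classifier to every voxel of the volume: each voxel
#' receives the forest's positive-class probability (fraction of trees
#' voting positive) for the 2D patch centered on it.  Slices are processed
#' independently; the output is dense and shape-aligned with the input.
#'
#' @param model a `patch_model`.
#' @param volume an [intensity_volume()].
#' @param slices optional subset of Z slices to predict (others stay 0).
#' @return A [probability_map()].
#' @export
predict_probability_map <- function(model, volume, slices = NULL) {
  N <- model$patch_size
  d <- dim(volume)
  if (N > 2L * min(d[2], d[3])) stop("patch size incompatible with volume")
  if (is.null(slices)) slices <- seq_len(d[1])
  out <- array(0, d)
  h <- (N - 1L) %/% 2L
  ys <- mirror_index(seq_len(d[2] + 2L * h) - h, d[2])
  xs <- mirror_index(seq_len(d[3] + 2L * h) - h, d[3])
  for (z in slices) {
    padded <- slice_of(volume, z)[ys, xs]
    X <- matrix(0, d[2] * d[3], N * N)
    k <- 0L
    for (dy in seq_len(N)) {       # row-major within patch: x offset fastest
      for (dx in seq_len(N)) {
        k <- k + 1L
        X[, k] <- as.vector(padded[dy:(dy + d[2] - 1L), dx:(dx + d[3] - 1L)])
      }
    }
    df <- as.data.frame(X)
    names(df) <- paste0("p", seq_len(ncol(X)))
    pr <- predict(model$forest, data = df, num.threads = 1L)$predictions[, "1"]
    out[z, , ] <- matrix(pr, d[2], d[3])
  }
  probability_map(out, spacing(volume))
}
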