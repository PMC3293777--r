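#' Contour centers
#'
#' The center of a contour is the average of all points on its circumference.
#'
#' @param contour contour record with an `xy` matrix (um).
#' @return Numeric `(x, y)` in micrometers.
#' @export
contour_center <- function(contour) {
  xy <- drop_repeated_vertex(contour$xy)
  colMeans(xy)
}

contour_feature_matrix <- function(contours) {
  if (length(contours) == 0) return(matrix(numeric(0), 0, 7))
  t(vapply(contours, function(ct) {
    if (is.null(ct$features)) stop("contour has no features; run contour_features() first")
    ct$features
  }, numeric(7)))
}

#' Enumerate gated contour pairs across adjacent planes
#'
#' Forms every pair `(a, b)` with `a` on plane `i` and `b` on plane `i + 1`
#' whose centers are strictly closer than the gate distance `D_um` in the XY
#' plane.  Each pair carries a 22-long feature vector: the 7 features of
#' `a`, the 7 features of `b`, the center distance, and the 7 signed
#' differences `a - b`.  Contours must already carry features (see
#' [contour_features()]).
#'
#' @param contours a `mitoseg_contours` list with `features` filled in.
#' @param D_um gate distance in micrometers (strict `<`).
#' @return List of class `mitoseg_pairs`; each element has `a`, `b` (indices
#'   into `contours`), `distance` and `features` (length 22).
#' @export
enumerate_pairs <- function(contours, D_um = 0.4) {
  planes <- vapply(contours, `[[`, integer(1), "plane")
  centers <- t(vapply(contours, contour_center, numeric(2)))
  fm <- contour_feature_matrix(contours)
  out <- list()
  for (pl in sort(unique(planes))) {
    ia <- which(planes == pl)
    ib <- which(planes == pl + 1L)
    if (length(ia) == 0 || length(ib) == 0) next
    for (i in ia) {
      d <- sqrt((centers[ib, 1] - centers[i, 1])^2 +
                (centers[ib, 2] - centers[i, 2])^2)
      for (k in which(d < D_um)) {
        j <- ib[k]
        out[[length(out) + 1L]] <- list(
          a = i, b = j, distance = unname(d[k]),
          features = unname(c(fm[i, ], fm[j, ], d[k], fm[i, ] - fm[j, ])))
      }
    }
  }
  structure(out, class = "mitoseg_pairs")
}

feature_names <- c("perimeter_um", "gray_contour", "prob_inside", "area_um2",
                   "ellipse_overlap", "ellipse_width_um", "ellipse_height_um")

pair_feature_matrix <- function(pairs) {
  if (length(pairs) == 0) return(matrix(numeric(0), 0, 22))
  m <- t(vapply(pairs, function(p) unname(p$features), numeric(22)))
  colnames(m) <- c(paste0("a_", feature_names), paste0("b_", feature_names),
                   "center_distance_um", paste0("d_", feature_names))
  m
}

#' @export
print.mitoseg_pairs <- function(x, ...) {
  cat(sprintf("<mitoseg_pairs> %d gated contour pairs\n", length(x)))
  invisible(x)
}

#' Rebalance contour training examples by positive duplication
#'
#' Appends `n` extra copies of every positive example (so each appears
#' `1 + n` times) while leaving negatives untouched; used to hold the
#' positive:negative ratio near 1:10 when positives are scarce.  Duplicates
#' are appended in original order after the input rows, so the output is
#' deterministic.
#'
#' @param x feature matrix, one row per example.
#' @param y binary labels (0/1).
#' @param n nonnegative number of duplicates per positive.
#' @return `list(x, y)` with duplicated positives.
#' @export
balance_training_pairs <- function(x, y, n = 0L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be nonnegative")
  if (n == 0L || !any(y == 1)) return(list(x = x, y = y))
  pos <- which(y == 1)
  idx <- c(seq_along(y), rep(pos, times = n))
  list(x = x[idx, , drop = FALSE], y = y[idx])
}

#' Train the contour-set classifier
#'
#' Fits a probability random forest on contour-set feature vectors: length 7
#' for single contours (`M = 1`) or length 22 for contour pairs (`M = 2`).
#'
#' @param x feature matrix (`n x 7` or `n x 22`).
#' @param y binary labels (1 = salient).
#' @param M contour-set size, 1 or 2.
#' @param rf_trees number of trees.
#' @param seed RNG seed.
#' @return A `contour_model` (wrapping a [ranger::ranger()] forest).
#' @export
train_contour_model <- function(x, y, M = 2L, rf_trees = 100L, seed = 1L) {
  if (!M %in% c(1L, 2L)) stop("M must be 1 or 2")
  want <- if (M == 2L) 22L else 7L
  if (ncol(x) != want) stop("feature length ", ncol(x), " does not match M = ", M,
                            " (expected ", want, ")")
  if (length(unique(y)) < 2) stop("both classes must be present")
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$y <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(y ~ ., data = df, num.trees = rf_trees,
                        probability = TRUE, seed = as.integer(seed),
                        num.threads = 1L)
  structure(list(forest = fit, M = as.integer(M), n_features = want,
                 counts = c(n_pos = sum(y == 1), n_neg = sum(y == 0)),
                 seed = as.integer(seed)),
            class = "contour_model")
}

predict_contour_prob <- function(model, x) {
  if (nrow(x) == 0) return(numeric(0))
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  predict(model$forest, data = df, num.threads = 1L)$predictions[, "1"]
}

#' @export
print.contour_model <- function(x, ...) {
  cat(sprintf("<contour_model> M = %d (%d features), %d trees, trained on %d+/%d-\n",
              x$M, x$n_features, x$forest$num.trees,
              x$counts["n_pos"], x$counts["n_neg"]))
  invisible(x)
}

#' Cross-validated saliency scores
#'
#' Stratified k-fold cross-validation of the contour-set classifier:
#' each example receives the saliency probability predicted by the forest
#' trained on the other folds.  Used to compare single-contour and
#' contour-pair classification by their ROC curves.
#'
#' @inheritParams train_contour_model
#' @param folds number of folds (default 5).
#' @return `list(scores, labels)` of out-of-fold probabilities.
#' @export
cv_contour_scores <- function(x, y, M = 2L, folds = 5L, rf_trees = 100L, seed = 1L) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  scores <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    if (length(unique(y[tr])) < 2) next
    m <- train_contour_model(x[tr, , drop = FALSE], y[tr], M = M,
                             rf_trees = rf_trees, seed = seed + f)
    scores[!tr] <- predict_contour_prob(m, x[!tr, , drop = FALSE])
  }
  list(scores = scores, labels = y)
}

#' Classify salient contours
#'
#' Applies the contour-set classifier and the probability threshold `T`.
#' For pairs (`M = 2`), pairs with probability `>= T` are kept and a contour
#' is salient when it participates in at least one kept pair.  For single
#' contours (`M = 1`), a contour is salient when its own probability is
#' `>= T`; pass the contours themselves (with features) as `pairs`.
#'
#' @param model a `contour_model`.
#' @param pairs a `mitoseg_pairs` list (M = 2) or `mitoseg_contours` (M = 1).
#' @param T probability threshold in `[0, 1]`.
#' @return List with `salient` (sorted indices of salient contours),
#'   `prob` (per pair/contour), and `kept` (logical).
#' @export
classify_salient <- function(model, pairs, T = 0.25) {
  if (model$M == 2L) {
    if (!inherits(pairs, "mitoseg_pairs")) stop("M = 2 model needs mitoseg_pairs")
    x <- pair_feature_matrix(pairs)
    prob <- predict_contour_prob(model, x)
    kept <- prob >= T
    sal <- sort(unique(unlist(lapply(pairs[kept], function(p) c(p$a, p$b)))))
  } else {
    x <- contour_feature_matrix(pairs)
    prob <- predict_contour_prob(model, x)
    kept <- prob >= T
    sal <- which(kept)
  }
  list(salient = as.integer(sal), prob = prob, kept = kept)
}
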