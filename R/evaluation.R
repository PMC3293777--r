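#' Voxelwise confusion counts
#'
#' @param pred,truth aligned binary volumes (0/1).
#' @return List of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  check_aligned(pred, truth)
  p <- as.vector(pred) != 0
  t <- as.vector(truth) != 0
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Pixel classification metrics
#'
#' True positive rate `TP/(TP+FN)`, false positive rate `FP/(FP+TN)` and
#' accuracy `(TP+TN)/(TP+FP+FN+TN)`.
#'
#' @param c a `confusion_counts` (or a list with TP/FP/FN/TN).
#' @return Named numeric `(tpr, fpr, accuracy)`.
#' @export
metrics <- function(c) {
  if (c$TP + c$FN == 0) stop("no positive truth voxels: TPR undefined")
  if (c$FP + c$TN == 0) stop("no negative truth voxels: FPR undefined")
  c(tpr = c$TP / (c$TP + c$FN),
    fpr = c$FP / (c$FP + c$TN),
    accuracy = (c$TP + c$TN) / (c$TP + c$FP + c$FN + c$TN))
}

# ROC points for a score vector: predict positive where score >= threshold.
roc_points <- function(scores, labels, thresholds) {
  pos <- labels != 0
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) stop("both truth classes must be present")
  o <- order(scores)
  s <- scores[o]; p <- pos[o]
  # counts of scores < thr via binary search on the sorted scores
  below <- findInterval(thresholds - 1e-12, s)
  cpos <- cumsum(p)
  cneg <- cumsum(!p)
  pos_below <- ifelse(below == 0, 0, cpos[pmax(below, 1)])
  neg_below <- ifelse(below == 0, 0, cneg[pmax(below, 1)])
  data.frame(threshold = thresholds,
             tpr = (npos - pos_below) / npos,
             fpr = (nneg - neg_below) / nneg)
}

#' ROC curve over a threshold grid
#'
#' One `(fpr, tpr)` point per threshold, predicting positive where
#' `scores >= threshold`.  Both coordinates are non-decreasing as the
#' threshold decreases.
#'
#' @param scores 3D array (or vector) of real scores.
#' @param truth aligned binary ground truth.
#' @param thresholds thresholds to evaluate.
#' @return `data.frame(threshold, tpr, fpr)` of class `roc_curve`.
#' @export
roc_curve <- function(scores, truth, thresholds = seq(0, 1, by = 0.02)) {
  if (!is.null(dim(scores))) check_aligned(scores, truth)
  rc <- roc_points(as.vector(scores), as.vector(truth), thresholds)
  class(rc) <- c("roc_curve", "data.frame")
  rc
}

#' Area under an ROC curve
#'
#' Trapezoidal area under `(fpr, tpr)` points, with `(0,0)` and `(1,1)`
#' appended.
#'
#' @param rc a `roc_curve` data frame.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(rc) {
  f <- c(1, rc$fpr, 0); t <- c(1, rc$tpr, 0)
  o <- order(f, t)
  f <- c(0, f[o], 1); t <- c(0, t[o], 1)
  sum(diff(f) * (head(t, -1) + t[-1]) / 2)
}

# Rank (Mann-Whitney) AUC of scores against binary labels.
score_auc <- function(scores, labels) {
  pos <- labels != 0
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Select the pair threshold T by error minimization
#'
#' Reproduces the published threshold-selection procedure: the first 7
#' slices of the labeled training volume train a full pipeline (patch
#' classifier, contours, pair classifier), the last 7 slices are segmented
#' end-to-end (including the level set) for every candidate `T` on the
#' grid, and the returned `T` minimizes the error
#' `E = alpha * FPR + beta * (1 - TPR)` on those test slices.  Ties break
#' toward larger `T` (fewer false positives, consistent with
#' `alpha >> beta`).
#'
#' @param volume labeled training [intensity_volume()] with >= 14 slices.
#' @param labels aligned [label_volume()].
#' @param config a [mitoseg_config()].
#' @return The selected `T`, with the full `data.frame(T, tpr, fpr, E)`
#'   attached as attribute `table`.
#' @export
select_threshold <- function(volume, labels, config = mitoseg_config()) {
  check_aligned(volume, labels)
  nz <- dim(volume)[1]
  if (nz < 14) stop("threshold selection needs at least 14 labeled slices")
  tr <- 1:7
  te <- (nz - 6):nz
  fit <- fit_components(subvolume(volume, tr), subvolume(labels, tr), config)
  ap <- apply_to_contours(fit, subvolume(volume, te), config)
  truth <- subvolume(labels, te)

  grid <- config$threshold_grid
  rows <- vector("list", length(grid))
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(grid)) {
    T <- grid[i]
    sal_ids <- salient_ids_at(ap, T)
    key <- paste0("k", paste(sal_ids, collapse = ","))
    if (is.null(cache[[key]])) {
      pred <- levelset_from_salient(ap, sal_ids, config)
      cache[[key]] <- metrics_or_zero(pred, truth)
    }
    m <- cache[[key]]
    rows[[i]] <- data.frame(T = T, tpr = m["tpr"], fpr = m["fpr"],
                            E = config$alpha * m["fpr"] + config$beta * (1 - m["tpr"]))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- max(tab$T[tab$E == min(tab$E)])   # tie-break toward larger T
  structure(best, table = tab)
}

metrics_or_zero <- function(pred, truth) {
  m <- confusion(pred, truth)
  if (m$TP + m$FN == 0 || m$FP + m$TN == 0) return(c(tpr = 0, fpr = 0, accuracy = NA))
  metrics(m)
}

subvolume <- function(vol, zidx) {
  v <- unclass(vol)[zidx, , , drop = FALSE]
  structure(v, spacing = spacing(vol), class = class(vol))
}
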