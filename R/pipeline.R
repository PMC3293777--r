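#' Fit the three-step segmentation pipeline
#'
#' Trains the full pipeline on a manually labeled volume:
#'
#' 1. a random-forest *patch classifier* on raw `N x N` pixel patches
#'    sampled from the labeled voxels, yielding a per-voxel probability map;
#' 2. isocontours of that map are detected, size-filtered, given ground-truth
#'    saliency by the 90%-interior rule, paired across adjacent planes
#'    within the gate distance, optionally rebalanced by positive
#'    duplication, and used to train the *contour-set classifier*;
#' 3. the pair threshold `T` is selected on a 7/7 slice split of the
#'    training data by minimizing `E = alpha * FPR + beta * (1 - TPR)` of
#'    the complete pipeline (see [select_threshold()]), unless
#'    `select_T = FALSE` keeps the configured `T`.
#'
#' The fitted object segments new volumes via [predict.mitoseg()], which
#' runs patch classification, salient-contour selection and the seeded
#' geodesic active contour.
#'
#' @param volume training [intensity_volume()].
#' @param labels aligned binary [label_volume()] (1 = mitochondrion).
#' @param config a [mitoseg_config()].
#' @param select_T run the threshold-selection procedure (needs >= 14
#'   slices); otherwise use `config$pair_threshold_T`.
#' @return An object of class `mitoseg`: list with `patch_model`,
#'   `contour_model`, `config` (with the selected `T`), and `provenance`.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_params(shape = c(16, 120, 120),
#'                                       n_organelles = 3, seed = 7))
#' cfg <- mitoseg_config(n_pos = 200, n_neg = 300, rf_trees = 50)
#' fit <- mitoseg(ph$intensity, ph$label, cfg, select_T = FALSE)
#' seg <- predict(fit, ph$intensity)
#' metrics(confusion(seg, ph$label))
#' }
#' @export
mitoseg <- function(volume, labels, config = mitoseg_config(), select_T = TRUE) {
  check_aligned(volume, labels)
  if (all(labels == 0)) stop("labels contain no positive voxels")
  t0 <- proc.time()[["elapsed"]]
  sel_tab <- NULL
  if (select_T) {
    T <- select_threshold(volume, labels, config)
    sel_tab <- attr(T, "table")
    config$pair_threshold_T <- as.numeric(T)
  }
  fit <- fit_components(volume, labels, config)
  structure(list(patch_model = fit$patch_model,
                 contour_model = fit$contour_model,
                 config = config,
                 selection_table = sel_tab,
                 training_contours = fit$contours,
                 training_gt = fit$contour_gt,
                 provenance = list(
                   n_train_slices = dim(volume)[1],
                   spacing = spacing(volume),
                   n_contours = length(fit$contours),
                   n_pairs = fit$n_pairs,
                   contour_counts = fit$contour_model$counts,
                   seed = config$seed,
                   elapsed_s = proc.time()[["elapsed"]] - t0)),
            class = "mitoseg")
}

# Train patch + contour classifiers on a labeled volume (no T selection).
fit_components <- function(volume, labels, config) {
  ts <- sample_training_patches(volume, labels, config$n_pos, config$n_neg,
                                config$patch_size, seed = config$seed)
  pm <- train_patch_model(ts, config$rf_trees, seed = config$seed + 1L)
  prob <- predict_probability_map(pm, volume)
  contours <- detect_and_featurize(prob, volume, config)
  gt <- vapply(contours, function(ct) {
    label_salient_ground_truth(ct, slice_of(labels, ct$plane),
                               config$saliency_fraction, spacing(volume)[2:3])
  }, integer(1))
  if (config$contour_set_size_M == 2L) {
    pairs <- enumerate_pairs(contours, config$pair_gate_D_um)
    if (length(pairs) == 0) stop("no gated contour pairs in the training volume")
    x <- pair_feature_matrix(pairs)
    y <- vapply(pairs, function(p) gt[p$a] * gt[p$b], integer(1))
  } else {
    pairs <- NULL
    x <- contour_feature_matrix(contours)
    y <- gt
  }
  bal <- balance_training_pairs(x, y, config$duplication_n)
  cm <- train_contour_model(bal$x, bal$y, M = config$contour_set_size_M,
                            rf_trees = config$rf_trees, seed = config$seed + 2L)
  list(patch_model = pm, contour_model = cm, contours = contours,
       contour_gt = gt, n_pairs = if (is.null(pairs)) length(contours) else length(pairs))
}

# Detect, size-filter and featurize contours of a probability map; contours
# whose interior rasterizes to nothing are dropped (they cannot be scored
# by the 90% rule nor seed the level set).
detect_and_featurize <- function(prob, volume, config) {
  sp_yx <- spacing(volume)[2:3]
  ref <- max(prob)
  all_ct <- list()
  for (z in seq_len(dim(prob)[1])) {
    ps <- slice_of(prob, z)
    if (ref <= 0 || min(ps) == max(ps)) next
    cts <- detect_isocontours(ps, config$iso_levels, sp_yx, ref = ref, plane = z)
    cts <- filter_by_perimeter(cts, config$perimeter_min_um, config$perimeter_max_um)
    rs <- slice_of(volume, z)
    for (ct in cts) {
      px <- polygon_interior_pixels(ct$xy, sp_yx, dim(ps))
      if (nrow(px) == 0) next
      ct$features <- contour_features(ct, rs, ps, sp_yx)
      ct$index <- length(all_ct) + 1L
      all_ct[[length(all_ct) + 1L]] <- ct
    }
  }
  structure(all_ct, class = "mitoseg_contours")
}

# Apply the trained classifiers to a new volume up to (but excluding) the
# threshold/level-set stage; the pieces are reused across candidate T.
apply_to_contours <- function(fit, volume, config) {
  prob <- predict_probability_map(fit$patch_model, volume)
  contours <- detect_and_featurize(prob, volume, config)
  if (config$contour_set_size_M == 2L) {
    pairs <- enumerate_pairs(contours, config$pair_gate_D_um)
    probs <- if (length(pairs) > 0)
      predict_contour_prob(fit$contour_model, pair_feature_matrix(pairs))
    else numeric(0)
  } else {
    pairs <- NULL
    probs <- if (length(contours) > 0)
      predict_contour_prob(fit$contour_model, contour_feature_matrix(contours))
    else numeric(0)
  }
  list(prob = prob, contours = contours, pairs = pairs, probs = probs,
       speed = edge_potential(prob, levelset_params_of(config)),
       volume_dim = dim(volume), spacing = spacing(volume))
}

salient_ids_at <- function(ap, T) {
  if (!is.null(ap$pairs)) {
    kept <- which(ap$probs >= T)
    sort(unique(unlist(lapply(ap$pairs[kept], function(p) c(p$a, p$b)))))
  } else {
    which(ap$probs >= T)
  }
}

levelset_from_salient <- function(ap, sal_ids, config) {
  seeds <- seeds_from_contours(structure(unclass(ap$contours)[sal_ids],
                                         class = "mitoseg_contours"),
                               ap$volume_dim, ap$spacing, config$erosion_px)
  if (sum(seeds) == 0) {
    return(label_volume(array(0L, ap$volume_dim), ap$spacing))
  }
  run_geodesic_active_contour(seeds, ap$speed, levelset_params_of(config),
                              ap$spacing)
}

levelset_params_of <- function(config) {
  levelset_params(advection = config$levelset_advection,
                  curvature = config$levelset_curvature,
                  propagation = config$levelset_propagation)
}

#' Segment a volume with a fitted pipeline
#'
#' Runs the three steps on a new volume: probability map, salient-contour
#' selection at the fitted threshold `T`, seeded geodesic active contour.
#' `type` selects what is returned; `"all"` exposes every intermediate
#' (probability map, detected contours, salient contour indices, seed mask
#' and final labels) for inspection.  Large volumes can be processed in
#' overlapping Z slabs that are OR-reassembled.
#'
#' @param object a fitted [mitoseg()] object.
#' @param volume an [intensity_volume()] with spacing compatible with
#'   training.
#' @param type `"label"` (default), `"prob"`, `"salient"`, `"contours"` or
#'   `"all"`.
#' @param slab_max_z if set, split the volume into Z slabs of at most this
#'   many slices (>= 2) and segment each independently.
#' @param slab_overlap slices of overlap between consecutive slabs.
#' @param ... unused.
#' @return Per `type`: a [label_volume()], a [probability_map()], a
#'   `mitoseg_contours`, or a list of intermediates.
#' @export
predict.mitoseg <- function(object, volume,
                            type = c("label", "prob", "salient", "contours", "all"),
                            slab_max_z = NULL, slab_overlap = 2L, ...) {
  type <- match.arg(type)
  if (!is.null(slab_max_z)) {
    if (type != "label") stop("slab processing returns labels only")
    slabs <- split_slabs(dim(volume)[1], slab_max_z, slab_overlap)
    parts <- lapply(seq_len(nrow(slabs)), function(i) {
      predict(object, subvolume(volume, slabs$start[i]:slabs$end[i]))
    })
    return(reassemble_slabs(parts, slabs, dim(volume), spacing(volume)))
  }
  config <- object$config
  ap <- apply_to_contours(object, volume, config)
  if (type == "prob") return(ap$prob)
  if (type == "contours") return(ap$contours)
  sal <- salient_ids_at(ap, config$pair_threshold_T)
  if (type == "salient") {
    return(structure(unclass(ap$contours)[sal], class = "mitoseg_contours"))
  }
  labels <- levelset_from_salient(ap, sal, config)
  if (type == "label") return(labels)
  list(prob_map = ap$prob, contours = ap$contours, pairs = ap$pairs,
       salient = sal, pair_prob = ap$probs, labels = labels)
}

#' Split a stack into overlapping Z slabs
#'
#' Slabs have full XY extent and at most `max_z` slices, consecutive slabs
#' overlapping by `overlap_z` so adjacent-plane contour pairing is
#' unaffected at slab borders.  The slabs cover every slice;
#' [reassemble_slabs()] merges per-slab labels by voxelwise OR.
#'
#' @param nz number of slices (or a volume).
#' @param max_z maximum slab thickness (>= 2).
#' @param overlap_z slices shared by consecutive slabs.
#' @return `data.frame(start, end)` of 1-based inclusive slice ranges.
#' @export
split_slabs <- function(nz, max_z, overlap_z = 2L) {
  if (!is.null(dim(nz))) nz <- dim(nz)[1]
  if (max_z < 2) stop("max_z must be >= 2")
  if (overlap_z < 0 || overlap_z >= max_z) stop("need 0 <= overlap_z < max_z")
  if (nz <= max_z) return(data.frame(start = 1L, end = as.integer(nz)))
  step <- max_z - overlap_z
  starts <- 1L
  while (starts[length(starts)] + max_z - 1L < nz) {
    starts <- c(starts, starts[length(starts)] + step)
  }
  data.frame(start = as.integer(starts),
             end = as.integer(pmin(starts + max_z - 1L, nz)))
}

#' @rdname split_slabs
#' @param parts list of per-slab [label_volume()]s.
#' @param slabs the `data.frame` returned by `split_slabs`.
#' @param full_dim `(z, y, x)` shape of the full volume.
#' @param spacing voxel spacing in nm.
#' @export
reassemble_slabs <- function(parts, slabs, full_dim, spacing) {
  out <- array(0L, full_dim)
  for (i in seq_along(parts)) {
    zidx <- slabs$start[i]:slabs$end[i]
    out[zidx, , ] <- pmax(out[zidx, , , drop = FALSE],
                          array(as.integer(unclass(parts[[i]])), dim = c(length(zidx), full_dim[2:3])))
  }
  label_volume(out, spacing)
}

#' @export
print.mitoseg <- function(x, ...) {
  cat("<mitoseg> three-step segmentation pipeline\n")
  cat(sprintf("  patch model:   %dx%d raw patches, %d trees (OOB AUC %.3f)\n",
              x$patch_model$patch_size, x$patch_model$patch_size,
              x$patch_model$rf_trees, x$patch_model$oob_auc))
  cat(sprintf("  contour model: M = %d, trained on %d+/%d- examples\n",
              x$contour_model$M, x$contour_model$counts["n_pos"],
              x$contour_model$counts["n_neg"]))
  cat(sprintf("  threshold T:   %.2f%s\n", x$config$pair_threshold_T,
              if (is.null(x$selection_table)) " (configured)" else " (selected)"))
  invisible(x)
}

#' @export
summary.mitoseg <- function(object, ...) {
  p <- object$provenance
  cat("Three-step mitochondria segmentation pipeline\n\n")
  print(object)
  cat(sprintf("\nTrained on %d slices (spacing %s nm), %d contours, %d contour sets\n",
              p$n_train_slices, paste(p$spacing, collapse = "x"),
              p$n_contours, p$n_pairs))
  if (!is.null(object$selection_table)) {
    cat("\nThreshold selection (E = alpha*FPR + beta*(1-TPR)):\n")
    print(object$selection_table, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Plot a slice with contour overlays
#'
#' Draws one XY slice of a volume in gray scale and overlays contours
#' (e.g. the salient set from [predict.mitoseg()]).
#'
#' @param x a fitted `mitoseg` object (used only for dispatch).
#' @param volume the volume to display.
#' @param z slice index.
#' @param contours optional `mitoseg_contours` to overlay.
#' @param ... passed to [graphics::image()].
#' @export
plot.mitoseg <- function(x, volume, z = 1L, contours = NULL, ...) {
  m <- slice_of(volume, z)
  sp <- spacing(volume)[2:3] / 1000
  xs <- (seq_len(ncol(m)) - 1) * sp[2]
  ys <- (seq_len(nrow(m)) - 1) * sp[1]
  graphics::image(xs, ys, t(m)[, rev(seq_len(nrow(m)))],
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "x (um)", ylab = "y (um)", ...)
  ymax <- max(ys)
  if (!is.null(contours)) {
    for (ct in contours) {
      if (ct$plane != z) next
      xy <- rbind(ct$xy, ct$xy[1, ])
      graphics::lines(xy[, 1], ymax - xy[, 2], col = "red", lwd = 1.5)
    }
  }
  invisible(x)
}
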