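# The study-geometry experiment (350 x 350 x 30 phantom, 15 training and 15
# testing slices, full threshold-selection grid), computed once and shared by
# the acceptance checks.  Heavy (~10 min on one core).

.study_env <- new.env(parent = emptyenv())

study_fixture <- function() {
  if (!is.null(.study_env$res)) return(.study_env$res)
  seed <- 1L
  ph <- generate_phantom(phantom_params(seed = seed))
  tr <- 1:15; te <- 16:30
  vol_tr <- mitoseg:::subvolume(ph$intensity, tr)
  lab_tr <- mitoseg:::subvolume(ph$label, tr)
  vol_te <- mitoseg:::subvolume(ph$intensity, te)
  lab_te <- mitoseg:::subvolume(ph$label, te)
  cfg <- mitoseg_config(seed = seed)
  fit <- mitoseg(vol_tr, lab_tr, cfg, select_T = TRUE)
  seg <- predict(fit, vol_te, type = "all")

  thr <- seq(0, 1, by = 0.02)
  roc_rf <- roc_curve(seg$prob_map, lab_te, thr)
  roc_int <- roc_curve((255 - unclass(vol_te)) / 255, lab_te, thr)

  sal_metrics <- function(sal_ids) {
    salmask <- array(0L, dim(vol_te))
    for (ct in unclass(seg$contours)[sal_ids]) {
      px <- mitoseg:::polygon_interior_pixels(ct$xy, spacing(vol_te)[2:3],
                                              dim(vol_te)[2:3])
      if (nrow(px) > 0) salmask[cbind(ct$plane, px[, 1], px[, 2])] <- 1L
    }
    metrics(confusion(label_volume(salmask, spacing(vol_te)), lab_te))
  }
  # salient set at the published default threshold (T = 0.25), independent of
  # the threshold the fit selected for itself
  kept <- which(seg$pair_prob >= 0.25)
  sal_default <- sort(unique(unlist(lapply(seg$pairs[kept],
                                           function(p) c(p$a, p$b)))))

  .study_env$res <- list(
    ph = ph, fit = fit, seg = seg,
    vol_te = vol_te, lab_te = lab_te,
    roc_rf = roc_rf, roc_int = roc_int,
    m_final = metrics(confusion(seg$labels, lab_te)),
    m_sal = sal_metrics(seg$salient),          # at the fitted T
    m_sal_default = sal_metrics(sal_default)   # at T = 0.25
  )
  .study_env$res
}

# Interpolated TPR of an ROC curve at given FPR values.
tpr_at_fpr <- function(rc, fpr) {
  o <- order(rc$fpr, rc$tpr)
  stats::approx(c(0, rc$fpr[o], 1), c(0, rc$tpr[o], 1), xout = fpr,
                ties = max, rule = 2)$y
}
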