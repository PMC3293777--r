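lv <- function(a) label_volume(a, c(50, 10, 10))

test_that("confusion counts match a hand tally", {
  truth <- array(0L, c(1, 4, 4)); truth[1, 1:2, ] <- 1L
  pred <- array(0L, c(1, 4, 4)); pred[1, 1:3, 1:2] <- 1L
  # hand tally: TP = rows 1:2 & cols 1:2 = 4; FP = row 3 cols 1:2 = 2;
  # FN = rows 1:2 cols 3:4 = 4; TN = 6
  cc <- confusion(lv(pred), lv(truth))
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(4, 2, 4, 6))

  same <- confusion(lv(truth), lv(truth))
  expect_equal(same$FP + same$FN, 0)
  expect_equal(unname(metrics(same)["accuracy"]), 1)
  inv <- confusion(lv(1L - truth), lv(truth))
  expect_equal(inv$TP + inv$TN, 0)
  expect_error(confusion(lv(pred), lv(array(0L, c(2, 4, 4)))), "aligned")
})

test_that("metrics implement the TPR/FPR/accuracy formulas", {
  m <- metrics(list(TP = 8, FN = 2, FP = 1, TN = 9))
  expect_equal(unname(m), c(0.8, 0.1, 0.85))
  truth <- array(rep(c(0L, 1L), 32), c(4, 4, 4))
  allneg <- metrics(confusion(lv(array(0L, c(4, 4, 4))), lv(truth)))
  expect_equal(unname(allneg["tpr"]), 0)
  expect_equal(unname(allneg["accuracy"]), 0.5)
  expect_error(metrics(list(TP = 0, FN = 0, FP = 1, TN = 9)), "positive")
})

test_that("ROC curves are monotone and hit the corner cases", {
  truth <- array(rep(c(0L, 1L), 500), c(10, 10, 10))
  rc <- roc_curve(array(as.numeric(truth), dim(truth)), lv(truth),
                  thresholds = c(-1, 0.5, 2))
  expect_equal(rc$tpr[rc$threshold == 0.5], 1)    # perfect scores pass (0, 1)
  expect_equal(rc$fpr[rc$threshold == 0.5], 0)
  expect_equal(c(rc$tpr[1], rc$fpr[1]), c(1, 1))  # threshold below all scores
  expect_equal(c(rc$tpr[3], rc$fpr[3]), c(0, 0))

  set.seed(40)
  for (rep in 1:3) {
    scores <- array(runif(1000), c(10, 10, 10))
    rc <- roc_curve(scores, lv(truth), seq(0, 1, 0.05))
    expect_true(all(diff(rc$tpr) <= 1e-12))       # non-increasing with threshold
    expect_true(all(diff(rc$fpr) <= 1e-12))
  }
  # scores independent of truth: AUC ~ 0.5
  set.seed(41)
  scores <- array(runif(8000), c(20, 20, 20))
  truth2 <- lv(array(rep(c(0L, 1L), 4000), c(20, 20, 20)))
  expect_equal(roc_auc(roc_curve(scores, truth2, seq(0, 1, 0.01))), 0.5,
               tolerance = 0.05)
})

test_that("rank AUC agrees with an independent implementation", {
  set.seed(52)
  scores <- runif(400)
  labels <- rbinom(400, 1, plogis(4 * (scores - 0.5)))
  got <- mitoseg:::score_auc(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("threshold selection minimizes E on the 7/7 split with larger-T ties", {
  ph <- generate_phantom(phantom_params(
    shape = c(14, 120, 120), n_organelles = 4,
    organelle_axes_xy_um = c(0.12, 0.25), organelle_axes_z_um = c(0.08, 0.15),
    n_membranes = 3, n_vesicles = 15, n_blobs = 1, seed = 23))
  cfg <- mitoseg_config(n_pos = 150, n_neg = 200, rf_trees = 40, seed = 23,
                        threshold_grid = c(0.1, 0.3, 0.5, 0.9))
  T <- select_threshold(ph$intensity, ph$label, cfg)
  tab <- attr(T, "table")
  expect_true(T %in% cfg$threshold_grid)
  expect_equal(tab$E, cfg$alpha * tab$fpr + cfg$beta * (1 - tab$tpr))
  expect_equal(as.numeric(T), max(tab$T[tab$E == min(tab$E)]))  # tie-break up

  # beta = 0: only false positives matter, ties break to the largest T
  cfg0 <- mitoseg_config(n_pos = 150, n_neg = 200, rf_trees = 40, seed = 23,
                         threshold_grid = c(0.1, 0.5, 1.0), beta = 0)
  T0 <- select_threshold(ph$intensity, ph$label, cfg0)
  tab0 <- attr(T0, "table")
  expect_equal(as.numeric(T0), max(tab0$T[tab0$fpr == min(tab0$fpr)]))

  expect_error(select_threshold(mitoseg:::subvolume(ph$intensity, 1:10),
                                mitoseg:::subvolume(ph$label, 1:10), cfg),
               "14")
})
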