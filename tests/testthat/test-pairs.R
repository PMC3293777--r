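featurize_toy <- function(ct) {
  ct$features <- contour_features(ct, matrix(100, 300, 300),
                                  matrix(0.5, 300, 300), c(10, 10))
  ct
}

test_that("pair enumeration applies the strict center-distance gate", {
  a <- featurize_toy(generate_toy_polygons("circle", 0.2, plane = 1,
                                           center_um = c(1, 1)))
  b <- featurize_toy(generate_toy_polygons("circle", 0.1, plane = 2,
                                           center_um = c(1, 1)))
  cts <- structure(list(a, b), class = "mitoseg_contours")
  pairs <- enumerate_pairs(cts, 0.4)
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$distance, 0)
  expect_length(pairs[[1]]$features, 22)
  # features assemble as [7(a), 7(b), distance, 7(a - b)]
  expect_equal(unname(pairs[[1]]$features),
               unname(c(a$features, b$features, 0, a$features - b$features)))

  far <- featurize_toy(generate_toy_polygons("circle", 0.1, plane = 2,
                                             center_um = c(1.5, 1)))
  pairs2 <- enumerate_pairs(structure(list(a, far), class = "mitoseg_contours"), 0.4)
  expect_length(pairs2, 0)   # centers 0.5 um apart, D = 0.4
})

test_that("gated pairs equal a brute-force all-pairs oracle", {
  set.seed(19)
  cts <- list()
  for (i in seq_len(30)) {
    cts[[i]] <- featurize_toy(generate_toy_polygons(
      "circle", runif(1, 0.05, 0.15), plane = sample(1:4, 1),
      center_um = c(runif(1, 0.5, 2.5), runif(1, 0.5, 2.5)), n_vertices = 40))
  }
  cts <- structure(cts, class = "mitoseg_contours")
  D <- 0.4
  pairs <- enumerate_pairs(cts, D)
  got <- t(vapply(pairs, function(p) c(p$a, p$b), numeric(2)))
  # oracle: exhaustive O(n^2) scan
  want <- NULL
  for (i in seq_along(cts)) for (j in seq_along(cts)) {
    if (cts[[j]]$plane != cts[[i]]$plane + 1L) next
    d <- sqrt(sum((contour_center(cts[[i]]) - contour_center(cts[[j]]))^2))
    if (d < D) want <- rbind(want, c(i, j))
  }
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               want[order(want[, 1], want[, 2]), , drop = FALSE])
})

test_that("positive duplication rebalances deterministically", {
  x <- matrix(seq_len(110 * 3), 110, 3)
  y <- rep(c(1L, 0L), c(10, 100))
  b0 <- balance_training_pairs(x, y, 0)
  expect_identical(b0$x, x)
  b6 <- balance_training_pairs(matrix(0, 200, 3), rep(c(1L, 0L), c(100, 100)), 6)
  expect_equal(sum(b6$y == 1), 700)
  expect_equal(sum(b6$y == 0), 100)
  bn <- balance_training_pairs(x, rep(0L, 110), 4)
  expect_identical(bn$x, x)
  expect_error(balance_training_pairs(x, y, -1), "nonnegative")
})

test_that("contour classifier separates separable features; permuted labels are chance", {
  set.seed(7)
  n <- 300
  x <- cbind(matrix(rnorm(n * 21), n, 21), c(rnorm(n / 2, -3), rnorm(n / 2, 3)))
  y <- rep(c(0L, 1L), each = n / 2)
  cv <- cv_contour_scores(x, y, M = 2, rf_trees = 60, seed = 3)
  expect_gt(mitoseg:::score_auc(cv$scores, cv$labels), 0.95)

  yp <- sample(y)
  cvp <- cv_contour_scores(x, yp, M = 2, rf_trees = 60, seed = 3)
  auc_p <- mitoseg:::score_auc(cvp$scores, cvp$labels)
  expect_gt(auc_p, 0.4)
  expect_lt(auc_p, 0.6)

  expect_error(train_contour_model(x, rep(1L, n), M = 2), "both classes")
  expect_error(train_contour_model(x[, 1:10], y, M = 2), "feature length")
  expect_error(train_contour_model(x, y, M = 1), "feature length")
})

test_that("the salient set grows monotonically as T decreases", {
  set.seed(12)
  n <- 80
  x <- cbind(matrix(rnorm(n * 21), n, 21), rnorm(n, rep(c(-1, 1), each = n / 2)))
  y <- rep(c(0L, 1L), each = n / 2)
  model <- train_contour_model(x, y, M = 2, rf_trees = 50, seed = 2)
  # fabricate a pairs object over 40 contours
  pairs <- lapply(seq_len(n), function(i) {
    list(a = sample(40, 1), b = sample(40, 1), distance = 0.1,
         features = x[i, ])
  })
  pairs <- structure(pairs, class = "mitoseg_pairs")
  prev <- NULL
  for (T in c(1.01, 0.75, 0.5, 0.25, 0)) {
    sal <- classify_salient(model, pairs, T)$salient
    if (!is.null(prev)) expect_true(all(prev %in% sal))
    prev <- sal
  }
  expect_length(classify_salient(model, pairs, 1.01)$salient, 0)
  all_gated <- sort(unique(unlist(lapply(pairs, function(p) c(p$a, p$b)))))
  expect_equal(classify_salient(model, pairs, 0)$salient, all_gated)
})
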