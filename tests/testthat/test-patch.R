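test_that("patch extraction flattens the N x N neighborhood row-major", {
  v <- intensity_volume(array(100L, c(2, 30, 30)), c(50, 10, 10))
  p <- extract_patch(v, 1, 15, 15, 11)
  expect_length(p, 121)
  expect_true(all(p == 100))
  expect_equal(extract_patch(v, 2, 4, 9, 1), 100)
  expect_error(extract_patch(v, 1, 15, 15, 10), "odd")
})

test_that("border patches equal an explicit mirror-padding oracle", {
  set.seed(8)
  m <- matrix(sample(0:255, 15 * 12, replace = TRUE), 15, 12)
  v <- intensity_volume(array(m, c(1, 15, 12)), c(50, 10, 10))
  N <- 7; h <- 3
  # independent oracle: build the padded matrix by explicit reflection
  refl <- function(n) c(rev(seq_len(h)), seq_len(n), n - seq_len(h) + 1L)
  pad <- m[refl(15), refl(12)]
  for (yx in list(c(1, 1), c(1, 12), c(15, 1), c(8, 6), c(15, 12))) {
    y <- yx[1]; x <- yx[2]
    want <- as.vector(t(pad[(y):(y + N - 1), (x):(x + N - 1)]))
    expect_equal(extract_patch(v, 1, y, x, N), want)
  }
})

test_that("training patch sampling is exact, stratified and seeded", {
  ph <- small_phantom()
  ts <- sample_training_patches(ph$intensity, ph$label, 120, 180, 11, seed = 3)
  expect_equal(nrow(ts$x), 300)
  expect_equal(sum(ts$y == 1), 120)
  expect_equal(sum(ts$y == 0), 180)
  expect_true(all(ph$label[ts$index[ts$y == 1]] == 1))
  expect_true(all(ph$label[ts$index[ts$y == 0]] == 0))
  ts2 <- sample_training_patches(ph$intensity, ph$label, 120, 180, 11, seed = 3)
  expect_identical(ts$index, ts2$index)
  expect_error(sample_training_patches(ph$intensity, ph$label, 10^7, 10, 11, 1),
               "positive")
})

test_that("the forest separates separable patches and rejects single-class input", {
  x <- rbind(matrix(0, 60, 25), matrix(255, 60, 25))
  ts <- structure(list(x = x, y = rep(c(1L, 0L), each = 60),
                       counts = c(n_pos = 60, n_neg = 60), patch_size = 5L,
                       seed = 1L), class = "patch_training_set")
  m <- train_patch_model(ts, 50, seed = 1)
  expect_gt(m$oob_auc, 0.99)
  pred <- predict(m$forest, data = as.data.frame(`names<-`(
    as.data.frame(x), paste0("p", 1:25))), num.threads = 1)$predictions[, "1"]
  expect_true(all((pred > 0.5) == (ts$y == 1)))   # training accuracy 1

  ts$y <- rep(0L, 120)
  expect_error(train_patch_model(ts, 10), "both classes")
})

test_that("permuted labels give chance-level out-of-bag AUC", {
  ph <- small_phantom()
  ts <- sample_training_patches(ph$intensity, ph$label, 150, 150, 11, seed = 21)
  m_real <- train_patch_model(ts, 80, seed = 2)
  expect_gt(m_real$oob_auc, 0.8)
  set.seed(31)
  ts$y <- sample(ts$y)
  m_null <- train_patch_model(ts, 80, seed = 2)
  expect_gt(m_null$oob_auc, 0.4)
  expect_lt(m_null$oob_auc, 0.6)
})

test_that("probability maps are dense, in [0, 1], shape-aligned and seeded", {
  ph <- small_phantom()
  ts <- sample_training_patches(ph$intensity, ph$label, 150, 200, 11, seed = 5)
  m <- train_patch_model(ts, 50, seed = 6)
  pr <- predict_probability_map(m, ph$intensity, slices = c(2, 5))
  expect_identical(dim(pr), dim(ph$intensity))
  expect_gte(min(pr), 0)
  expect_lte(max(pr), 1)
  pr2 <- predict_probability_map(m, ph$intensity, slices = c(2, 5))
  expect_identical(unclass(pr), unclass(pr2))
  # a model trained on bright-vs-dark grays scores a dark slice low
  x <- rbind(matrix(255, 50, 121), matrix(0, 50, 121))
  tss <- structure(list(x = x, y = rep(c(1L, 0L), each = 50),
                        counts = c(n_pos = 50, n_neg = 50), patch_size = 11L,
                        seed = 1L), class = "patch_training_set")
  ms <- train_patch_model(tss, 50, seed = 1)
  dark <- intensity_volume(array(0L, c(1, 20, 20)), c(50, 10, 10))
  expect_true(all(predict_probability_map(ms, dark) < 0.5))
})
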