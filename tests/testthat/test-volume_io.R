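test_that("stack write/read round-trips 8-bit volumes losslessly", {
  set.seed(42)
  v <- intensity_volume(array(sample(0:255, 4 * 20 * 16, replace = TRUE),
                              c(4, 20, 16)), c(50, 10, 10))
  dir_png <- file.path(tempdir(), "stack_png")
  write_stack(v, dir_png)
  back <- read_stack(dir_png, spacing = c(50, 10, 10))
  expect_identical(dim(back), dim(v))
  expect_true(all(back == v))

  f_tif <- file.path(tempdir(), "stack.tif")
  write_stack(v, f_tif)
  back2 <- read_stack(f_tif, spacing = c(50, 10, 10))
  expect_true(all(back2 == v))
  unlink(dir_png, recursive = TRUE); unlink(f_tif)
})

test_that("directory stacks keep lexicographic slice order and shape", {
  dir <- file.path(tempdir(), "ordered")
  dir.create(dir, showWarnings = FALSE)
  for (z in 1:15) {
    png::writePNG(matrix(z / 255, 12, 10), file.path(dir, sprintf("s_%04d.png", z)))
  }
  v <- read_stack(dir, spacing = c(50, 10, 10))
  expect_identical(dim(v), c(15L, 12L, 10L))
  expect_equal(as.vector(v[, 1, 1]), 1:15)
  unlink(dir, recursive = TRUE)
})

test_that("single-slice TIFF reads as a (1, H, W) volume", {
  f <- file.path(tempdir(), "one.tif")
  tiff::writeTIFF(matrix(0.5, 7, 9), f, bits.per.sample = 8L)
  v <- read_stack(f)
  expect_identical(dim(v), c(1L, 7L, 9L))
  unlink(f)
})

test_that("labels are stored as 0/255 on disk and re-binarized on read", {
  lab <- label_volume(array(0L, c(4, 4, 4)), c(50, 10, 10))
  d0 <- file.path(tempdir(), "lab0")
  write_stack(lab, d0)
  expect_equal(max(read_stack(d0)), 0)

  lab1 <- label_volume(array(1L, c(4, 4, 4)), c(50, 10, 10))
  d1 <- file.path(tempdir(), "lab1")
  write_stack(lab1, d1)
  expect_equal(min(read_stack(d1)), 255)         # raw stored values
  expect_true(all(read_stack(d1, labels = TRUE) == 1))
  unlink(c(d0, d1), recursive = TRUE)
})

test_that("bad stacks are rejected with descriptive errors", {
  expect_error(read_stack(file.path(tempdir(), "nope-missing")), "no such")
  dir <- file.path(tempdir(), "mixed")
  dir.create(dir, showWarnings = FALSE)
  png::writePNG(matrix(0, 5, 5), file.path(dir, "a.png"))
  png::writePNG(matrix(0, 6, 5), file.path(dir, "b.png"))
  expect_error(read_stack(dir), "inconsistent")
  unlink(dir, recursive = TRUE)
})

test_that("volume constructors enforce their invariants", {
  expect_error(intensity_volume(matrix(0, 2, 2), c(50, 10, 10)), "3D")
  expect_error(intensity_volume(array(0, c(2, 2, 2)), c(50, 10)), "spacing")
  expect_error(intensity_volume(array(0, c(2, 2, 2)), c(0, 10, 10)), "spacing")
  expect_error(label_volume(array(2, c(2, 2, 2)), c(50, 10, 10)), "binary")
  expect_error(probability_map(array(1.5, c(2, 2, 2)), c(50, 10, 10)), "0, 1")
  v <- intensity_volume(array(0L, c(2, 3, 4)), c(70, 10, 10))
  expect_equal(spacing(v), c(70, 10, 10))
})
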