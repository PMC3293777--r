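test_that("seed masks are eroded contour interiors", {
  sp <- c(50, 10, 10)
  big <- generate_toy_polygons("circle", 0.25, plane = 2, center_um = c(0.6, 0.6),
                               n_vertices = 180)  # 25 px radius
  small <- generate_toy_polygons("circle", 0.08, plane = 4, center_um = c(0.6, 0.6))
  cts <- structure(list(big, small), class = "mitoseg_contours")
  seeds <- seeds_from_contours(cts, c(5, 120, 120), sp, erosion_px = 10)
  # disc r=25 eroded by 10 ~ disc r=15 (morphology oracle)
  expect_equal(sum(seeds[2, , ]), pi * 15^2, tolerance = 0.05)
  expect_equal(sum(seeds[4, , ]), 0)              # r=8 over-eroded to nothing
  expect_equal(sum(seeds[c(1, 3, 5), , ]), 0)     # only the contours' planes

  # independent morphology oracle: EBImage disc erosion of the same interior
  px <- mitoseg:::polygon_interior_pixels(big$xy, sp[2:3], c(120, 120))
  m <- matrix(0L, 120, 120); m[px] <- 1L
  # brush discretization differs slightly from the exact Euclidean disc
  ref <- EBImage::erode(m, EBImage::makeBrush(21, "disc"))
  expect_equal(sum(seeds[2, , ]), sum(ref), tolerance = 0.06)
})

test_that("gradient magnitude matches the analytic gradient of a quadratic field", {
  d <- c(7, 20, 24)
  z <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  x <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  f <- 2 * x^2 + 3 * y^2 - z^2 + x * 1.5
  g <- gradient_magnitude(structure(f, spacing = c(50, 10, 10)), step = c(1, 1, 1))
  want <- sqrt((4 * x + 1.5)^2 + (6 * y)^2 + (2 * z)^2)
  core <- 2:(d[1] - 1)
  expect_equal(g[core, 2:(d[2] - 1), 2:(d[3] - 1)],
               want[core, 2:(d[2] - 1), 2:(d[3] - 1)], tolerance = 1e-6)
})

test_that("edge potential is maximal on flat maps and minimal on edges", {
  sp <- c(50, 10, 10)
  flat <- probability_map(array(0.4, c(3, 20, 20)), sp)
  g <- edge_potential(flat)
  expect_equal(length(unique(round(as.vector(g), 10))), 1)  # uniform
  expect_gt(min(g), 0.9)

  step <- array(0, c(3, 20, 20)); step[, , 11:20] <- 1
  gs <- edge_potential(probability_map(step, sp))
  edge_cols <- 10:11
  expect_lt(max(gs[2, 10, edge_cols]), min(gs[2, 10, c(1:8, 13:20)]))
  expect_true(all(gs > 0 & gs <= 1))
})

test_that("empty seeds yield empty labels with a warning", {
  seeds <- label_volume(array(0L, c(3, 10, 10)), c(50, 10, 10))
  expect_warning(out <- run_geodesic_active_contour(seeds, array(1, c(3, 10, 10))),
                 "no seed")
  expect_true(all(out == 0))
})

test_that("propagation-only evolution grows monotonically from seeds", {
  d <- c(5, 40, 40)
  seeds <- array(0L, d); seeds[3, 18:22, 18:22] <- 1L
  sv <- label_volume(seeds, c(50, 10, 10))
  sp1 <- array(1, d)
  p1 <- levelset_params(advection = 0, curvature = 0, propagation = 1,
                        max_iterations = 1, rms_tolerance = 1e-12)
  o1 <- run_geodesic_active_contour(sv, sp1, p1, c(50, 10, 10))
  expect_equal(sum(o1), sum(seeds))               # 1 iteration ~ the seeds
  p50 <- levelset_params(advection = 0, curvature = 0, propagation = 1,
                         max_iterations = 50, rms_tolerance = 1e-12)
  o50 <- run_geodesic_active_contour(sv, sp1, p50, c(50, 10, 10))
  p100 <- levelset_params(advection = 0, curvature = 0, propagation = 1,
                          max_iterations = 100, rms_tolerance = 1e-12)
  o100 <- run_geodesic_active_contour(sv, sp1, p100, c(50, 10, 10))
  expect_true(all(o50[seeds == 1] == 1))
  expect_true(all(o100[o50 == 1] == 1))           # monotone growth
  expect_gt(sum(o100), sum(o50))
})

test_that("the seeded evolution fills a blob and stops at its boundary", {
  fx <- blob_fixture(d = c(9, 80, 80), r_px = 20)
  d <- dim(fx$prob)
  seeds <- array(0L, d)
  yy <- matrix(seq_len(d[2]), d[2], d[3])
  xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
  seeds[5, , ][(yy - d[2] / 2)^2 + (xx - d[3] / 2)^2 <= 10^2] <- 1L
  sv <- label_volume(seeds, spacing(fx$prob))
  out <- run_geodesic_active_contour(sv, edge_potential(fx$prob),
                                     levelset_params(), spacing(fx$prob))
  m <- metrics(confusion(out, fx$truth))
  seed_tpr <- metrics(confusion(sv, fx$truth))["tpr"]
  expect_gt(m["tpr"], seed_tpr)                   # grows beyond the seeds
  expect_gt(m["tpr"], 0.9)                        # fills the blob
  expect_lt(m["fpr"], 0.05)                       # pinned at the boundary
  expect_error(run_geodesic_active_contour(sv, array(1, c(2, 2, 2))), "shape")
})
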