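test_that("isocontour detection matches closed forms on a smooth disc", {
  m <- disc_slice(101, r_px = 25)   # 0.5-level circle of radius 0.25 um
  cts <- detect_isocontours(m, 0.5, c(10, 10), ref = 1)
  expect_length(cts, 1)
  expect_equal(polygon_perimeter(cts[[1]]$xy), 2 * pi * 0.25, tolerance = 0.02)
  expect_equal(polygon_area(cts[[1]]$xy), pi * 0.25^2, tolerance = 0.02)
  # all-zero slice: nothing to detect
  expect_length(detect_isocontours(matrix(0, 20, 20), c(0.5), c(10, 10), ref = 1), 0)
  expect_error(detect_isocontours(matrix(0, 5, 5), c(0.5, 0.3), c(10, 10)),
               "increasing")
})

test_that("border-touching contours are closed along the border", {
  # disc centered on the top border: interior should be about half the disc
  m <- disc_slice(101, cy = 1, cx = 51, r_px = 30)
  cts <- detect_isocontours(m, 0.5, c(10, 10), ref = 1)
  expect_length(cts, 1)
  px <- mitoseg:::polygon_interior_pixels(cts[[1]]$xy, c(10, 10), c(101, 101))
  expect_equal(nrow(px), pi * 30^2 / 2, tolerance = 0.06)
})

test_that("the perimeter filter keeps exactly the in-range contours", {
  cts <- structure(lapply(c(0.3, 0.7, 5.0, 7.0), circle_of_perimeter),
                   class = "mitoseg_contours")
  kept <- filter_by_perimeter(cts, 0.6, 6.0)
  expect_length(kept, 2)
  expect_length(filter_by_perimeter(structure(list(), class = "mitoseg_contours"),
                                    0.6, 6), 0)
  expect_length(filter_by_perimeter(kept, 0.6, 6), 2)   # identity when in range
  expect_error(filter_by_perimeter(cts, 6, 0.6), "min_um")
})

test_that("contour features match closed forms and rasterization oracles", {
  raw <- matrix(100, 400, 400)
  pr <- matrix(0.5, 400, 400)
  sq <- contour_features(generate_toy_polygons("square", 1), raw, pr, c(10, 10))
  expect_length(sq, 7)
  expect_equal(unname(sq["perimeter_um"]), 4)
  expect_equal(unname(sq["area_um2"]), 1)
  expect_equal(unname(sq["gray_contour"]), 100)
  expect_equal(unname(sq["prob_inside"]), 0.5)
  expect_lt(sq["ellipse_overlap"], 1)

  el <- contour_features(generate_toy_polygons("ellipse", 0.4, n_vertices = 100),
                         raw, pr, c(10, 10))
  expect_gt(el["ellipse_overlap"], 0.98)         # self-fit
  expect_equal(unname(el["ellipse_width_um"]), 0.8, tolerance = 0.02)
  expect_equal(unname(el["ellipse_height_um"]), 0.4, tolerance = 0.02)

  st <- contour_features(generate_toy_polygons("irregular", 0.5, n_vertices = 120),
                         raw, pr, c(10, 10))
  expect_lt(st["ellipse_overlap"], sq["ellipse_overlap"])

  bad <- list(plane = 1L, xy = rbind(c(0, 0), c(1, 1), c(0, 0)))
  expect_error(contour_features(bad, raw, pr, c(10, 10)), "degenerate")
})

test_that("ground-truth saliency implements the interior-fraction rule", {
  lab <- matrix(0L, 120, 120)
  lab[30:90, 30:90] <- 1L
  inside <- generate_toy_polygons("circle", 0.15, center_um = c(0.6, 0.6))
  expect_equal(label_salient_ground_truth(inside, lab, 0.9, c(10, 10)), 1L)
  expect_equal(label_salient_ground_truth(inside, matrix(0L, 120, 120), 0.9,
                                          c(10, 10)), 0L)
  # half-covered contour: interior fraction ~0.5 < 0.9
  half <- matrix(0L, 120, 120)
  half[, 1:60] <- 1L
  straddle <- generate_toy_polygons("circle", 0.15, center_um = c(0.595, 0.6))
  expect_equal(label_salient_ground_truth(straddle, half, 0.9, c(10, 10)), 0L)
  far <- generate_toy_polygons("circle", 0.002, center_um = c(0.55, 0.55))
  expect_error(label_salient_ground_truth(far, lab, 0.9, c(100, 100)), "empty")
})
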