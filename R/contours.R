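#' Polygon geometry helpers
#'
#' Perimeter (arc length of the closed polygon) and area (shoelace formula)
#' of a polygon given as an `n x 2` matrix of `(x, y)` vertices in
#' micrometers.  A repeated final vertex is tolerated.
#'
#' @param xy `n x 2` matrix of vertices (columns x, y), micrometers.
#' @return Length in micrometers / area in square micrometers.
#' @export
polygon_perimeter <- function(xy) {
  xy <- drop_repeated_vertex(xy)
  d <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2))
  sum(d)
}

#' @rdname polygon_perimeter
#' @export
polygon_area <- function(xy) {
  xy <- drop_repeated_vertex(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:length(x), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

drop_repeated_vertex <- function(xy) {
  n <- nrow(xy)
  if (n > 1 && all(abs(xy[1, ] - xy[n, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  xy
}

# Rasterize the interior of a polygon (vertices in um) on a (ny, nx) pixel
# grid with pixel pitch (hy, hx) in nm; pixel centers sit at
# ((i-1)*hy, (j-1)*nm).  Returns 1-based (row, col) index matrix of pixels
# whose centers are strictly inside (even-odd rule).
polygon_interior_pixels <- function(xy, spacing_yx_nm, dims_yx) {
  xy <- drop_repeated_vertex(xy)
  hy <- spacing_yx_nm[1] / 1000; hx <- spacing_yx_nm[2] / 1000
  vy <- xy[, 2] / hy   # 0-based pixel coordinates
  vx <- xy[, 1] / hx
  y0 <- max(0L, as.integer(floor(min(vy))))
  x0 <- max(0L, as.integer(floor(min(vx))))
  y1 <- min(dims_yx[1] - 1L, as.integer(ceiling(max(vy))))
  x1 <- min(dims_yx[2] - 1L, as.integer(ceiling(max(vx))))
  if (y1 < y0 || x1 < x0) return(matrix(integer(0), 0, 2))
  m <- .poly_fill(vy, vx, y0, y1 - y0 + 1L, x0, x1 - x0 + 1L)
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) == 0) return(matrix(integer(0), 0, 2))
  cbind(w[, 1] + y0, w[, 2] + x0)   # 1-based because which() is 1-based
}

# Bilinear sampling of matrix m at 0-based pixel coordinates (ypx, xpx).
bilinear_sample <- function(m, ypx, xpx) {
  ny <- nrow(m); nx <- ncol(m)
  ypx <- pmin(pmax(ypx, 0), ny - 1)
  xpx <- pmin(pmax(xpx, 0), nx - 1)
  y0 <- pmin(floor(ypx), ny - 2); y0 <- pmax(y0, 0)
  x0 <- pmin(floor(xpx), nx - 2); x0 <- pmax(x0, 0)
  fy <- ypx - y0; fx <- xpx - x0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1); i11 <- cbind(y0 + 2, x0 + 2)
  m[i00] * (1 - fy) * (1 - fx) + m[i01] * (1 - fy) * fx +
    m[i10] * fy * (1 - fx) + m[i11] * fy * fx
}

#' Detect isocontours of a probability slice
#'
#' Extracts all closed level curves of a 2D probability slice at each level
#' `l * ref`, where `ref` defaults to the maximum of the slice (pass the
#' global probability-map maximum to threshold relative to the whole map).
#' Curves are traced with marching squares (subpixel linear interpolation)
#' and returned in physical micrometer coordinates.  Open curves that touch
#' the image border are closed along the border, choosing the closure whose
#' interior has the higher mean slice value (i.e. the one enclosing the
#' above-threshold region).  Contours from all levels are pooled; no
#' deduplication is attempted.
#'
#' @param prob_slice `(y, x)` matrix of values.
#' @param levels strictly increasing fractions in (0, 1).
#' @param spacing pixel pitch `(y, x)` in nm.
#' @param ref reference intensity the levels are fractions of.
#' @param plane Z plane index recorded on each contour.
#' @return A list of contour records (`plane`, `index`, `iso_level`, `xy`),
#'   class `mitoseg_contours`.
#' @export
detect_isocontours <- function(prob_slice, levels, spacing = c(10, 10),
                               ref = max(prob_slice), plane = 1L) {
  if (length(prob_slice) == 0) stop("empty slice")
  if (any(levels <= 0) || any(levels >= 1) || any(diff(levels) <= 0)) {
    stop("levels must be strictly increasing in (0, 1)")
  }
  ny <- nrow(prob_slice); nx <- ncol(prob_slice)
  hy <- spacing[1] / 1000; hx <- spacing[2] / 1000
  row_um <- (seq_len(ny) - 1) * hy
  col_um <- (seq_len(nx) - 1) * hx
  out <- list()
  for (lv in levels) {
    thr <- lv * ref
    if (thr <= min(prob_slice) || thr >= max(prob_slice)) next
    cls <- grDevices::contourLines(row_um, col_um, prob_slice, levels = thr)
    for (cl in cls) {
      xy <- cbind(x = cl$y, y = cl$x)
      if (nrow(xy) < 3) next
      xy <- close_contour(xy, prob_slice, spacing)
      if (is.null(xy) || nrow(xy) < 3) next
      out[[length(out) + 1L]] <- list(plane = as.integer(plane),
                                      index = length(out) + 1L,
                                      iso_level = lv, xy = xy)
    }
  }
  structure(out, class = "mitoseg_contours")
}

# Close a traced curve: already-closed loops get their duplicate endpoint
# dropped; border-touching open curves are completed along the image border
# (inserting corners), picking of the two possible closures the one whose
# interior mean is larger (ties: smaller area).
close_contour <- function(xy, slice, spacing) {
  n <- nrow(xy)
  if (all(abs(xy[1, ] - xy[n, ]) < 1e-9)) return(xy[-n, , drop = FALSE])
  hy <- spacing[1] / 1000; hx <- spacing[2] / 1000
  X <- (ncol(slice) - 1) * hx
  Y <- (nrow(slice) - 1) * hy
  eps <- 0.51 * max(hx, hy)
  on_border <- function(p) p[1] < eps || p[1] > X - eps || p[2] < eps || p[2] > Y - eps
  if (!on_border(xy[1, ]) || !on_border(xy[n, ])) {
    return(xy)  # rare open curve not at the border: implicit closure
  }
  snap <- function(p) {
    if (p[1] < eps) p[1] <- 0 else if (p[1] > X - eps) p[1] <- X
    if (p[2] < eps) p[2] <- 0 else if (p[2] > Y - eps) p[2] <- Y
    p
  }
  xy[1, ] <- snap(xy[1, ]); xy[n, ] <- snap(xy[n, ])
  P <- 2 * (X + Y)
  # position along the border walked counterclockwise from (0,0)
  tpos <- function(p) {
    if (abs(p[2]) < 1e-12 && p[1] < X) return(p[1])                 # bottom
    if (abs(p[1] - X) < 1e-12 && p[2] < Y) return(X + p[2])         # right
    if (abs(p[2] - Y) < 1e-12 && p[1] > 0) return(X + Y + (X - p[1]))  # top
    2 * X + Y + (Y - p[2])                                          # left
  }
  corner_t <- c(bottomright = X, topright = X + Y, topleft = 2 * X + Y, bottomleft = P)
  corner_p <- rbind(c(X, 0), c(X, Y), c(0, Y), c(0, 0))
  border_path <- function(t1, t2) {  # corners passed walking t1 -> t2 (ccw)
    len <- (t2 - t1) %% P
    ts <- (corner_t - t1) %% P
    ord <- order(ts)
    sel <- ts[ord] > 1e-9 & ts[ord] < len - 1e-9
    corner_p[ord, , drop = FALSE][sel, , drop = FALSE]
  }
  t_end <- tpos(xy[n, ]); t_start <- tpos(xy[1, ])
  bp_ccw <- border_path(t_end, t_start)          # walk the border one way...
  bp_cw <- border_path(t_start, t_end)           # ...or the other
  cand <- list(rbind(xy, bp_ccw),
               rbind(xy, bp_cw[rev(seq_len(nrow(bp_cw))), , drop = FALSE]))
  score <- vapply(cand, function(p) {
    px <- polygon_interior_pixels(p, spacing, dim(slice))
    if (nrow(px) == 0) return(-Inf)
    mean(slice[px])
  }, numeric(1))
  if (all(!is.finite(score))) return(NULL)
  if (abs(score[1] - score[2]) < 1e-12) {
    areas <- vapply(cand, polygon_area, numeric(1))
    cand[[which.min(areas)]]
  } else {
    cand[[which.max(score)]]
  }
}

#' Filter contours by perimeter
#'
#' Retains exactly the contours whose perimeter lies in
#' `[min_um, max_um]` (boundary inclusive).  Extreme sizes cannot plausibly
#' outline a mitochondrion and are removed before classification.
#'
#' @param contours a `mitoseg_contours` list.
#' @param min_um,max_um perimeter bounds in micrometers.
#' @return The surviving contours (same class).
#' @export
filter_by_perimeter <- function(contours, min_um = 0.6, max_um = 6.0) {
  if (min_um >= max_um) stop("need min_um < max_um")
  per <- vapply(contours, function(ct) polygon_perimeter(ct$xy), numeric(1))
  structure(unclass(contours)[per >= min_um & per <= max_um],
            class = "mitoseg_contours")
}

#' Seven contour features
#'
#' Computes the feature vector used by the contour classifier:
#' perimeter (um), mean raw gray sampled at the contour vertices, mean
#' probability over the rasterized interior, area (um^2, shoelace), ellipse
#' overlap (intersection over union between the interior and the interior of
#' the best-fit ellipse), and the full width and height (major and minor
#' axes) of that ellipse.  The ellipse is fit to the vertices by direct
#' least squares; degenerate fits fall back to a moment-based ellipse.
#'
#' @param contour a contour record with an `xy` vertex matrix (um).
#' @param raw_slice `(y, x)` matrix of raw gray values.
#' @param prob_slice `(y, x)` matrix of probabilities.
#' @param spacing pixel pitch `(y, x)` in nm.
#' @return Named numeric vector of length 7.
#' @export
contour_features <- function(contour, raw_slice, prob_slice, spacing = c(10, 10)) {
  xy <- drop_repeated_vertex(contour$xy)
  if (nrow(unique(xy)) < 3) stop("degenerate polygon: fewer than 3 distinct vertices")
  hy <- spacing[1] / 1000; hx <- spacing[2] / 1000
  per <- polygon_perimeter(xy)
  area <- polygon_area(xy)
  gray <- mean(bilinear_sample(raw_slice, xy[, 2] / hy, xy[, 1] / hx))
  px <- polygon_interior_pixels(xy, spacing, dim(prob_slice))
  prob_in <- if (nrow(px) > 0) mean(prob_slice[px]) else
    mean(bilinear_sample(prob_slice, mean(xy[, 2]) / hy, mean(xy[, 1]) / hx))
  el <- fit_ellipse(xy)
  exy <- ellipse_polygon(el)
  ov <- raster_overlap(xy, exy, spacing, dim(prob_slice))
  c(perimeter_um = per, gray_contour = gray, prob_inside = prob_in,
    area_um2 = area, ellipse_overlap = ov,
    ellipse_width_um = 2 * el$a, ellipse_height_um = 2 * el$b)
}

# Intersection-over-union of two polygon interiors rasterized on a common
# pixel grid large enough to hold both (clipped to the slice extent).
raster_overlap <- function(xy1, xy2, spacing, dims_yx) {
  hy <- spacing[1] / 1000; hx <- spacing[2] / 1000
  pad_dims <- c(max(dims_yx[1], ceiling(max(xy1[, 2], xy2[, 2]) / hy) + 2),
                max(dims_yx[2], ceiling(max(xy1[, 1], xy2[, 1]) / hx) + 2))
  p1 <- polygon_interior_pixels(xy1, spacing, pad_dims)
  p2 <- polygon_interior_pixels(xy2, spacing, pad_dims)
  if (nrow(p1) == 0 || nrow(p2) == 0) return(0)
  k1 <- p1[, 1] + pad_dims[1] * p1[, 2]
  k2 <- p2[, 1] + pad_dims[1] * p2[, 2]
  inter <- length(intersect(k1, k2))
  uni <- length(union(k1, k2))
  inter / uni
}

#' Fit an ellipse to polygon vertices
#'
#' Direct least-squares conic fit constrained to ellipses (numerically
#' stable variant); when the fit is degenerate (collinear or near-degenerate
#' vertex sets) a moment-based ellipse with the same vertex covariance is
#' returned instead.
#'
#' @param xy `n x 2` matrix of vertices.
#' @return List with `cx`, `cy`, `a` (semi-major), `b` (semi-minor), `angle`.
#' @export
fit_ellipse <- function(xy) {
  xy <- drop_repeated_vertex(xy)
  x <- xy[, 1]; y <- xy[, 2]
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  fit <- if (nrow(xy) >= 6) {
    tryCatch(fit_ellipse_hf(xs, ys), error = function(e) NULL)
  } else NULL  # the conic fit is rank-deficient below 6 vertices
  if (is.null(fit) || fit$a / fit$b > 50) return(fit_ellipse_moments(xy))
  fit$cx <- fit$cx + mx
  fit$cy <- fit$cy + my
  fit
}

# Halir & Flusser's numerically stable direct ellipse fit on centered data.
fit_ellipse_hf <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  ev <- Re(e$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  k <- which(cond > 0)
  if (length(k) == 0) stop("no elliptical solution")
  a1 <- ev[, k[1]]
  coef <- c(a1, Tm %*% a1)   # A, B, C, D, E, F for Ax^2+Bxy+Cy^2+Dx+Ey+F
  conic_to_ellipse(coef)
}

conic_to_ellipse <- function(cf) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  a2 <- num / (den * (-(A + C) - s))
  b2 <- num / (den * (-(A + C) + s))
  if (!is.finite(a2) || !is.finite(b2) || a2 <= 0 || b2 <= 0) stop("degenerate ellipse")
  a <- sqrt(max(a2, b2)); b <- sqrt(min(a2, b2))
  angle <- if (abs(B) < 1e-12 && A <= C) 0
           else if (abs(B) < 1e-12) pi / 2
           else atan2(C - A - s, B)
  list(cx = cx, cy = cy, a = a, b = b, angle = angle)
}

fit_ellipse_moments <- function(xy) {
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  ctr <- sweep(xy, 2, c(cx, cy))
  cv <- crossprod(ctr) / nrow(xy)   # population moments
  e <- eigen(cv, symmetric = TRUE)
  # uniform samples of an ellipse outline have variance a^2/2 on the major axis
  a <- sqrt(2 * max(e$values[1], 1e-12))
  b <- sqrt(2 * max(e$values[2], 1e-12))
  list(cx = cx, cy = cy, a = a, b = b,
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

ellipse_polygon <- function(el, n = 120L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ca <- cos(el$angle); sa <- sin(el$angle)
  u <- el$a * cos(t); v <- el$b * sin(t)
  cbind(x = el$cx + u * ca - v * sa, y = el$cy + u * sa + v * ca)
}

#' Ground-truth saliency of a contour
#'
#' A detected contour is a ground-truth positive when at least `fraction`
#' (default 90%) of the pixels strictly inside it are labeled positive in
#' the manual segmentation.
#'
#' @param contour contour record with `xy` in micrometers.
#' @param label_slice `(y, x)` binary matrix of manual labels.
#' @param fraction required labeled fraction of interior pixels.
#' @param spacing pixel pitch `(y, x)` in nm.
#' @return `1L` or `0L`.
#' @export
label_salient_ground_truth <- function(contour, label_slice, fraction = 0.9,
                                       spacing = c(10, 10)) {
  px <- polygon_interior_pixels(contour$xy, spacing, dim(label_slice))
  if (nrow(px) == 0) stop("empty interior after rasterization")
  as.integer(mean(label_slice[px]) >= fraction)
}

#' @export
print.mitoseg_contours <- function(x, ...) {
  cat(sprintf("<mitoseg_contours> %d contours on %d plane(s)\n", length(x),
              length(unique(vapply(x, `[[`, integer(1), "plane")))))
  invisible(x)
}

#' @export
as.data.frame.mitoseg_contours <- function(x, ...) {
  if (length(x) == 0) {
    return(data.frame(plane = integer(0), iso_level = numeric(0),
                      n_vertices = integer(0), perimeter_um = numeric(0)))
  }
  data.frame(
    plane = vapply(x, `[[`, integer(1), "plane"),
    iso_level = vapply(x, `[[`, numeric(1), "iso_level"),
    n_vertices = vapply(x, function(ct) nrow(ct$xy), integer(1)),
    perimeter_um = vapply(x, function(ct) polygon_perimeter(ct$xy), numeric(1))
  )
}
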