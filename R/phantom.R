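#' Parameters of the synthetic EM phantom
#'
#' The phantom emulates the statistical structure of serial block-face SEM
#' neuropil at 10 nm XY / 50 nm Z sampling: dark striped ellipsoidal
#' organelles (mitochondria-like, cristae texture) embedded in a lighter
#' background crossed by dark membrane-like curves and scattered with small
#' dark vesicle discs plus a few untextured dark blobs, with additive
#' Gaussian noise.  The default volume is 350 x 350 voxels in XY and 30
#' slices in Z, matching typical desk-scale training/testing slabs.
#'
#' @param shape volume shape `(z, y, x)` in voxels.
#' @param spacing voxel size `(z, y, x)` in nm.
#' @param n_organelles number of labeled ellipsoidal organelles.
#' @param organelle_axes_xy_um range of in-plane ellipsoid semi-axes
#'   (micrometers); defaults chosen so most equatorial cross-section
#'   perimeters fall inside the 0.6--6 um contour gate.
#' @param organelle_axes_z_um range of the Z semi-axis (micrometers).
#' @param organelle_gray dark base gray level inside organelles.
#' @param cristae_period_px period (pixels) of the interior stripe texture.
#' @param cristae_contrast gray-level lift of the bright stripes.
#' @param n_membranes number of membrane-like dark curves.
#' @param membrane_gray,membrane_width_px membrane gray level and half-width.
#' @param n_vesicles number of small dark vesicle discs.
#' @param vesicle_radius_px range of vesicle radii in pixels.
#' @param vesicle_gray vesicle gray level.
#' @param n_blobs number of untextured dark confuser blobs (not labeled).
#' @param blob_radius_um range of blob radii (micrometers).
#' @param blob_gray blob gray level.
#' @param background_gray mean background gray level.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param seed RNG seed; the same seed reproduces the phantom bit-exactly.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(30, 350, 350),
                           spacing = c(50, 10, 10),
                           n_organelles = 12,
                           organelle_axes_xy_um = c(0.20, 0.50),
                           organelle_axes_z_um = c(0.15, 0.30),
                           organelle_gray = 60,
                           cristae_period_px = 6,
                           cristae_contrast = 55,
                           n_membranes = 8,
                           membrane_gray = 60,
                           membrane_width_px = 2,
                           n_vesicles = 60,
                           vesicle_radius_px = c(3, 8),
                           vesicle_gray = 70,
                           n_blobs = 5,
                           blob_radius_um = c(0.12, 0.20),
                           blob_gray = 70,
                           background_gray = 165,
                           noise_sigma = 12,
                           seed = 1L) {
  p <- as.list(environment())
  if (length(p$shape) != 3L || any(p$shape < 1)) stop("shape must be (z, y, x) >= 1")
  if (p$organelle_gray >= p$background_gray) {
    stop("organelles must be darker than the background")
  }
  if (p$n_organelles < 0) stop("n_organelles must be nonnegative")
  structure(p, class = "phantom_params")
}

#' Generate a synthetic EM phantom with ground truth
#'
#' Builds an intensity volume and the exactly aligned binary label volume
#' (1 on every voxel inside a generated organelle ellipsoid).  Deterministic
#' given `params$seed`.
#'
#' @param params a [phantom_params()] list.
#' @return `list(intensity = intensity_volume, label = label_volume)`.
#' @examples
#' ph <- generate_phantom(phantom_params(shape = c(6, 80, 80), n_organelles = 1,
#'                                       organelle_axes_xy_um = c(0.15, 0.2)))
#' mean(ph$label)
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  hz <- p$spacing[1]; hy <- p$spacing[2]; hx <- p$spacing[3]
  # largest organelle must fit
  if (p$n_organelles > 0) {
    need_xy <- 2 * min(p$organelle_axes_xy_um) * 1000
    need_z <- 2 * min(p$organelle_axes_z_um) * 1000
    if (need_xy > ny * hy || need_xy > nx * hx || need_z > nz * hz) {
      stop("infeasible geometry: organelle larger than the volume")
    }
  }

  with_seed(p$seed, {
    img <- array(p$background_gray, c(nz, ny, nx))
    lab <- array(0L, c(nz, ny, nx))

    img <- paint_membranes(img, p)
    img <- paint_vesicles(img, p)
    img <- paint_blobs(img, p)
    res <- paint_organelles(img, lab, p)
    img <- res$img; lab <- res$lab

    img <- img + rnorm(length(img), 0, p$noise_sigma)
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), c(nz, ny, nx))
    list(intensity = intensity_volume(img, p$spacing),
         label = label_volume(lab, p$spacing))
  })
}

# Uniform draw that degrades to the midpoint when the range is inverted
# (objects clamped to barely fit the volume).
runif_between <- function(lo, hi) {
  if (hi <= lo) (lo + hi) / 2 else runif(1, lo, hi)
}

# Ellipsoids with in-plane rotation and sinusoidal cristae stripes.
paint_organelles <- function(img, lab, p) {
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  hz <- p$spacing[1]; hy <- p$spacing[2]; hx <- p$spacing[3]
  for (k in seq_len(p$n_organelles)) {
    a <- runif(1, p$organelle_axes_xy_um[1], p$organelle_axes_xy_um[2]) * 1000 # nm
    b <- runif(1, p$organelle_axes_xy_um[1], p$organelle_axes_xy_um[2]) * 1000
    c_ <- runif(1, p$organelle_axes_z_um[1], p$organelle_axes_z_um[2]) * 1000
    # clamp so the ellipsoid fits inside the volume (with a 1-voxel margin)
    a <- min(a, (nx - 3) * hx / 2, (ny - 3) * hy / 2)
    b <- min(b, (nx - 3) * hx / 2, (ny - 3) * hy / 2)
    c_ <- min(c_, (nz - 3) * hz / 2)
    th <- runif(1, 0, pi)                        # in-plane orientation
    sa <- runif(1, 0, pi)                        # stripe orientation
    phase <- runif(1, 0, 2 * pi)
    # center, with margins so the ellipsoid fits
    mx <- max(a, b) / hx; my <- max(a, b) / hy; mzv <- c_ / hz
    cz <- runif(1, 1 + mzv, nz - mzv)
    cy <- runif(1, 1 + my, ny - my)
    cx <- runif(1, 1 + mx, nx - mx)
    z0 <- max(1L, floor(cz - mzv)); z1 <- min(nz, ceiling(cz + mzv))
    y0 <- max(1L, floor(cy - my)); y1 <- min(ny, ceiling(cy + my))
    x0 <- max(1L, floor(cx - mx)); x1 <- min(nx, ceiling(cx + mx))
    ys <- y0:y1; xs <- x0:x1
    dy <- (ys - cy) * hy
    dxm <- matrix((xs - cx) * hx, length(ys), length(xs), byrow = TRUE)
    dym <- matrix(dy, length(ys), length(xs))
    u <- dxm * cos(th) + dym * sin(th)
    v <- -dxm * sin(th) + dym * cos(th)
    stripes <- sin(2 * pi * (dxm * cos(sa) + dym * sin(sa)) /
                   (p$cristae_period_px * hx) + phase) > 0
    tex <- p$organelle_gray + p$cristae_contrast * stripes
    for (z in z0:z1) {
      fz <- 1 - ((z - cz) * hz / c_)^2
      if (fz <= 0) next
      inside <- (u / a)^2 + (v / b)^2 <= fz
      if (!any(inside)) next
      sl <- img[z, ys, xs]
      sl[inside] <- tex[inside]
      img[z, ys, xs] <- sl
      lz <- lab[z, ys, xs]
      lz[inside] <- 1L
      lab[z, ys, xs] <- lz
    }
  }
  list(img = img, lab = lab)
}

# Wavy dark curves spanning the slice, drifting slowly in Z; half are
# oriented along x, half along y.
paint_membranes <- function(img, p) {
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  w <- p$membrane_width_px
  for (k in seq_len(p$n_membranes)) {
    along_x <- runif(1) < 0.5
    n_main <- if (along_x) nx else ny
    n_perp <- if (along_x) ny else nx
    off <- runif(1, 0.1, 0.9) * n_perp
    amp <- runif(1, 5, 30)
    lam <- runif(1, 60, 200)
    ph <- runif(1, 0, 2 * pi)
    slope <- runif(1, -0.3, 0.3)
    drift <- runif(1, -2, 2)
    t <- seq_len(n_main)
    for (z in seq_len(nz)) {
      ctr <- off + amp * sin(2 * pi * t / lam + ph) + slope * (t - n_main / 2) +
        drift * (z - 1)
      for (d in -w:w) {
        idx <- round(ctr) + d
        ok <- idx >= 1 & idx <= n_perp
        if (along_x) {
          img[cbind(z, idx[ok], t[ok])] <- p$membrane_gray
        } else {
          img[cbind(z, t[ok], idx[ok])] <- p$membrane_gray
        }
      }
    }
  }
  img
}

# Small dark discs spanning one or two slices.
paint_vesicles <- function(img, p) {
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  for (k in seq_len(p$n_vesicles)) {
    r <- runif(1, p$vesicle_radius_px[1], p$vesicle_radius_px[2])
    r <- min(r, (ny - 3) / 2, (nx - 3) / 2)
    cz <- sample.int(nz, 1)
    cy <- runif_between(1 + r, ny - r)
    cx <- runif_between(1 + r, nx - r)
    ys <- floor(cy - r):ceiling(cy + r)
    xs <- floor(cx - r):ceiling(cx + r)
    dym <- matrix(ys - cy, length(ys), length(xs))
    dxm <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
    inside <- dym^2 + dxm^2 <= r^2
    sl <- img[cz, ys, xs]
    sl[inside] <- p$vesicle_gray
    img[cz, ys, xs] <- sl
  }
  img
}

# Untextured dark near-spherical blobs: confusers for plain intensity
# thresholding that carry no cristae texture and are NOT labeled.
paint_blobs <- function(img, p) {
  nz <- p$shape[1]; ny <- p$shape[2]; nx <- p$shape[3]
  hz <- p$spacing[1]; hy <- p$spacing[2]; hx <- p$spacing[3]
  for (k in seq_len(p$n_blobs)) {
    r <- runif(1, p$blob_radius_um[1], p$blob_radius_um[2]) * 1000  # nm
    r <- min(r, (nz - 3) * hz / 2, (ny - 3) * hy / 2, (nx - 3) * hx / 2)
    rz <- r / hz; ry <- r / hy; rx <- r / hx
    cz <- runif_between(1 + rz, nz - rz)
    cy <- runif_between(1 + ry, ny - ry)
    cx <- runif_between(1 + rx, nx - rx)
    zs <- max(1L, floor(cz - rz)):min(nz, ceiling(cz + rz))
    ys <- floor(cy - ry):ceiling(cy + ry)
    xs <- floor(cx - rx):ceiling(cx + rx)
    dym <- matrix((ys - cy) * hy, length(ys), length(xs))
    dxm <- matrix((xs - cx) * hx, length(ys), length(xs), byrow = TRUE)
    for (z in zs) {
      f <- r^2 - ((z - cz) * hz)^2
      if (f <= 0) next
      inside <- dym^2 + dxm^2 <= f
      sl <- img[z, ys, xs]
      sl[inside] <- p$blob_gray
      img[z, ys, xs] <- sl
    }
  }
  img
}

#' Toy polygons with known geometry
#'
#' Closed simple polygons with analytically known perimeter and area, used as
#' fixtures for the contour feature computations.
#'
#' @param kind `"circle"`, `"ellipse"`, `"square"` or `"irregular"` (a
#'   jittered star).
#' @param size_um characteristic size in micrometers: circle radius, ellipse
#'   semi-major axis (semi-minor is half), square side, star outer radius.
#' @param plane Z plane index the polygon lives on.
#' @param n_vertices number of vertices for the curved shapes.
#' @param center_um polygon center `(x, y)` in micrometers.
#' @param seed RNG seed (used only by `"irregular"`).
#' @return A contour record: list with `plane`, `iso_level` (`NA`) and an
#'   `xy` matrix of closed-polygon vertices in micrometers.
#' @examples
#' p <- generate_toy_polygons("circle", 0.2, n_vertices = 360)
#' polygon_perimeter(p$xy)  # ~ 2 * pi * 0.2
#' @export
generate_toy_polygons <- function(kind = c("circle", "ellipse", "square", "irregular"),
                                  size_um, plane = 1L, n_vertices = 120L,
                                  center_um = c(2, 2) * size_um, seed = 1L) {
  kind <- match.arg(kind)
  if (size_um <= 0) stop("size_um must be positive")
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  xy <- switch(kind,
    circle = cbind(x = size_um * cos(t), y = size_um * sin(t)),
    ellipse = cbind(x = size_um * cos(t), y = (size_um / 2) * sin(t)),
    square = {
      s <- size_um / 2
      cbind(x = c(-s, s, s, -s), y = c(-s, -s, s, s))
    },
    irregular = with_seed(seed, {
      n <- 10L
      ang <- seq(0, 2 * pi, length.out = 2 * n + 1L)[-(2 * n + 1L)]
      r <- rep(c(size_um, 0.4 * size_um), n) * runif(2 * n, 0.9, 1.1)
      cbind(x = r * cos(ang), y = r * sin(ang))
    })
  )
  xy[, 1] <- xy[, 1] + center_um[1]
  xy[, 2] <- xy[, 2] + center_um[2]
  list(plane = as.integer(plane), iso_level = NA_real_, xy = xy)
}
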