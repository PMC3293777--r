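#' Level-set parameters
#'
#' Scalings and numerical controls of the geodesic active contour.  The
#' default scalings (advection 160, curvature 6.75, propagation 1) are the
#' published operating point; derivatives are computed in units of the XY
#' pixel pitch with Z scaled by the anisotropy ratio, so the scalings keep
#' their pixel-based meaning on anisotropic grids.
#'
#' @param advection,curvature,propagation nonnegative term scalings.
#' @param max_iterations iteration cap of the evolution.
#' @param rms_tolerance stop when the RMS level-set update (in pixel units)
#'   falls below this.
#' @param band half-width (pixels) of the active narrow band.
#' @param reinit_every reinitialize the signed distance every this many
#'   iterations (0 = never).
#' @param sigmoid_alpha,sigmoid_beta parameters of the decreasing sigmoid
#'   mapping gradient magnitude to speed; `NULL` = auto-scaled from the
#'   observed gradient range (see [edge_potential()]).
#' @return List of class `levelset_params`.
#' @export
levelset_params <- function(advection = 160, curvature = 6.75, propagation = 1,
                            max_iterations = 2000L, rms_tolerance = 0.002,
                            band = 6, reinit_every = 50L,
                            sigmoid_alpha = NULL, sigmoid_beta = NULL) {
  if (advection < 0 || curvature < 0 || propagation < 0) {
    stop("scalings must be nonnegative")
  }
  if (max_iterations < 0) stop("max_iterations must be nonnegative")
  structure(list(advection = advection, curvature = curvature,
                 propagation = propagation,
                 max_iterations = as.integer(max_iterations),
                 rms_tolerance = rms_tolerance, band = band,
                 reinit_every = as.integer(reinit_every),
                 sigmoid_alpha = sigmoid_alpha, sigmoid_beta = sigmoid_beta),
            class = "levelset_params")
}

# Grid steps in units of the XY pixel pitch: (z_ratio, 1, hx/hy).
pixel_spacing <- function(sp) c(sp[1] / sp[2], 1, sp[3] / sp[2])

#' Spacing-aware gradient magnitude
#'
#' Central-difference gradient magnitude of a 3D field, with one-sided
#' differences at the faces.  Steps are taken in units of the XY pixel
#' pitch (Z scaled by the anisotropy ratio) so downstream level-set
#' scalings stay pixel-based.
#'
#' @param vol 3D array with a `spacing` attribute (nm), e.g. a
#'   [probability_map()].
#' @param step optional explicit `(z, y, x)` grid steps overriding the
#'   pixel-pitch convention.
#' @return 3D array of gradient magnitudes.
#' @export
gradient_magnitude <- function(vol, step = NULL) {
  if (is.null(step)) step <- pixel_spacing(spacing(vol))
  a <- unclass(vol)
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    ip <- pmin(seq_len(d[ax]) + 1L, d[ax])
    im <- pmax(seq_len(d[ax]) - 1L, 1L)
    den <- (ip - im) * step[ax]
    if (ax == 1) {
      gi <- (a[ip, , , drop = FALSE] - a[im, , , drop = FALSE]) / den
    } else if (ax == 2) {
      gi <- (a[, ip, , drop = FALSE] - a[, im, , drop = FALSE]) /
        rep(rep(den, each = d[1]), times = d[3])
    } else {
      gi <- (a[, , ip, drop = FALSE] - a[, , im, drop = FALSE]) /
        rep(den, each = d[1] * d[2])
    }
    g2 <- g2 + gi^2
  }
  sqrt(g2)
}

#' Edge potential (speed image) from a probability map
#'
#' Computes the spacing-aware gradient magnitude of the probability map and
#' maps it monotonically decreasingly into (0, 1] with a sigmoid, so that
#' high gradient (organelle boundary) means low speed.  The level set then
#' tends to fill homogeneous-probability regions and halt at boundaries.
#' When `sigmoid_alpha`/`sigmoid_beta` are `NULL` they are auto-scaled to
#' the observed gradient range: `beta = K/2`, `alpha = K/8` with `K` the
#' 99th percentile of the positive gradient magnitudes.
#'
#' The gradient entering the edge potential is taken in index units (one
#' step per voxel along every axis): on Z-sparse stacks the inter-slice
#' probability change happens across a single step, and dividing it by the
#' physical anisotropy ratio would underweight Z boundaries by that factor
#' and let the level set escape through the top and bottom of organelles.
#'
#' @param prob a [probability_map()].
#' @param params a [levelset_params()].
#' @return 3D array of speeds in (0, 1], aligned with `prob`, with the
#'   gradient magnitude attached as attribute `gradmag`.
#' @export
edge_potential <- function(prob, params = levelset_params()) {
  g <- gradient_magnitude(prob, step = c(1, 1, 1))
  pos <- g[g > 0]
  if (length(pos) == 0) {
    speed <- array(1, dim(g))   # constant map: maximal uniform speed
  } else {
    K <- as.numeric(quantile(pos, 0.99))
    beta <- if (is.null(params$sigmoid_beta)) K / 2 else params$sigmoid_beta
    alpha <- if (is.null(params$sigmoid_alpha)) K / 8 else params$sigmoid_alpha
    speed <- 1 / (1 + exp((g - beta) / alpha))
  }
  attr(speed, "gradmag") <- g
  attr(speed, "spacing") <- spacing(prob)
  speed
}

#' Seed mask from salient contours
#'
#' Rasterizes the interior of every salient contour on its plane, erodes it
#' in-plane with a Euclidean disc of radius `erosion_px` pixels, and unions
#' the surviving voxels into a 3D binary seed mask.  Contours too small to
#' survive the erosion simply contribute nothing.
#'
#' @param contours a `mitoseg_contours` list of the salient contours.
#' @param volume_shape `(z, y, x)` shape of the target volume.
#' @param spacing voxel spacing `(z, y, x)` in nm.
#' @param erosion_px erosion radius in pixels.
#' @return A [label_volume()] seed mask.
#' @export
seeds_from_contours <- function(contours, volume_shape, spacing = c(50, 10, 10),
                                erosion_px = 10L) {
  seeds <- array(0L, volume_shape)
  dims_yx <- volume_shape[2:3]
  for (ct in contours) {
    z <- ct$plane
    if (z < 1 || z > volume_shape[1]) stop("contour plane outside the volume")
    px <- polygon_interior_pixels(ct$xy, spacing[2:3], dims_yx)
    if (nrow(px) == 0) next
    if (erosion_px > 0) px <- erode_pixels(px, dims_yx, erosion_px)
    if (nrow(px) == 0) next
    seeds[cbind(z, px[, 1], px[, 2])] <- 1L
  }
  label_volume(seeds, spacing)
}

# Erode a pixel set with a Euclidean disc of radius r: a pixel survives when
# its distance to the nearest pixel outside the set exceeds r.
erode_pixels <- function(px, dims_yx, r) {
  y0 <- max(1L, min(px[, 1]) - 1L); y1 <- min(dims_yx[1], max(px[, 1]) + 1L)
  x0 <- max(1L, min(px[, 2]) - 1L); x1 <- min(dims_yx[2], max(px[, 2]) + 1L)
  ny <- y1 - y0 + 1L; nx <- x1 - x0 + 1L
  inside <- array(1L, c(1L, ny, nx))
  inside[cbind(1L, px[, 1] - y0 + 1L, px[, 2] - x0 + 1L)] <- 0L
  # pixels on the bbox frame count as outside so border contours erode too
  d <- .edt3d(inside, c(1, 1, 1))   # distance to nearest outside pixel
  keep <- which(d[1, , ] > r, arr.ind = TRUE)
  if (length(keep) == 0) return(matrix(integer(0), 0, 2))
  if (is.null(dim(keep))) keep <- matrix(keep, ncol = 2)
  cbind(keep[, 1] + y0 - 1L, keep[, 2] + x0 - 1L)
}

# Signed distance (negative inside) from a binary seed mask, in units of the
# XY pixel pitch.
signed_distance <- function(mask, spacing_px) {
  m <- (unclass(mask) != 0) * 1L
  dim(m) <- dim(mask)
  d_out <- .edt3d(m, spacing_px)               # distance to nearest seed
  inv <- 1L - m
  dim(inv) <- dim(mask)
  d_in <- .edt3d(inv, spacing_px)              # distance to nearest non-seed
  phi <- d_out - d_in
  dim(phi) <- dim(mask)
  phi
}

#' Run the seeded geodesic active contour
#'
#' Initializes a level set as the signed distance from the seed mask and
#' evolves it under propagation, curvature and advection with the
#' configured scalings on the edge-potential speed image, until the RMS
#' update falls below tolerance or the iteration cap is reached.  Interior
#' voxels of the converged level set are returned as binary labels.
#'
#' @param seeds a [label_volume()] seed mask (from [seeds_from_contours()]).
#' @param speed speed image from [edge_potential()] (or any array in (0, 1]
#'   aligned with the seeds).
#' @param params a [levelset_params()].
#' @param spacing voxel spacing `(z, y, x)` in nm.
#' @return A [label_volume()]; attributes `iterations` and `rms` report the
#'   evolution.  Empty seeds yield empty labels with a warning.
#' @export
run_geodesic_active_contour <- function(seeds, speed, params = levelset_params(),
                                        spacing = attr(seeds, "spacing")) {
  if (!identical(dim(seeds), dim(speed))) stop("seeds and speed shapes differ")
  if (sum(seeds) == 0) {
    warning("no seed voxels: returning empty labels")
    out <- label_volume(array(0L, dim(seeds)), spacing)
    attr(out, "iterations") <- 0L
    return(out)
  }
  sp_px <- pixel_spacing(spacing)
  phi <- signed_distance(seeds, sp_px)
  # Growth phase: propagation + advection only.  Seeds start as one-voxel-thin
  # plates whose Z curvature is huge; evolving curvature from the start would
  # collapse them before they can grow into 3D bodies (the classical pipeline
  # avoids this by growing seeds with a fast-march stage first).
  it1 <- 0L
  if (params$curvature > 0 && params$max_iterations > 1L) {
    res <- .gac_evolve(phi, as.double(speed), sp_px,
                       params$propagation, 0, params$advection,
                       params$max_iterations, params$rms_tolerance,
                       params$band, params$reinit_every)
    phi <- res$phi
    it1 <- res$iterations
  }
  # Smoothing phase: all three terms at the configured scalings.
  res <- .gac_evolve(phi, as.double(speed), sp_px,
                     params$propagation, params$curvature, params$advection,
                     params$max_iterations, params$rms_tolerance,
                     params$band, params$reinit_every)
  lab <- (res$phi < 0) * 1L
  dim(lab) <- dim(seeds)
  out <- label_volume(lab, spacing)
  attr(out, "iterations") <- it1 + res$iterations
  attr(out, "rms") <- res$rms
  out
}
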