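# Shared fixtures, built in code.

# A small labeled phantom plus a fitted pipeline, computed once per test run.
.small_env <- new.env(parent = emptyenv())

small_phantom <- function() {
  if (is.null(.small_env$ph)) {
    .small_env$ph <- generate_phantom(phantom_params(
      shape = c(14, 160, 160), n_organelles = 4,
      organelle_axes_xy_um = c(0.15, 0.30), organelle_axes_z_um = c(0.10, 0.20),
      n_membranes = 4, n_vesicles = 25, n_blobs = 2, seed = 11))
  }
  .small_env$ph
}

small_fit <- function() {
  if (is.null(.small_env$fit)) {
    ph <- small_phantom()
    cfg <- mitoseg_config(n_pos = 250, n_neg = 350, rf_trees = 60, seed = 11)
    .small_env$fit <- mitoseg(ph$intensity, ph$label, cfg, select_T = FALSE)
  }
  .small_env$fit
}

# A smooth radial bump whose 0.5-level set is a circle of radius r_px.
disc_slice <- function(n = 101, cy = (n + 1) / 2, cx = (n + 1) / 2, r_px = 25) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  m <- r_px + 0.5 - r
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# Circle polygon of a given perimeter (for the size filter tests).
circle_of_perimeter <- function(p_um, plane = 1L) {
  generate_toy_polygons("circle", p_um / (2 * pi), plane = plane, n_vertices = 90)
}

# A synthetic ellipsoidal probability blob with aligned truth, for seeded
# level-set tests: (list of prob map, truth labels).
blob_fixture <- function(d = c(9, 80, 80), r_px = 20, sp = c(50, 10, 10)) {
  prob <- array(0.05, d)
  zc <- (d[1] + 1) / 2
  for (z in seq_len(d[1])) {
    fz <- 1 - ((z - zc) / (zc - 0.5))^2
    if (fz <= 0) next
    yy <- matrix(seq_len(d[2]), d[2], d[3])
    xx <- matrix(seq_len(d[3]), d[2], d[3], byrow = TRUE)
    r2 <- ((yy - d[2] / 2) / r_px)^2 + ((xx - d[3] / 2) / r_px)^2
    sl <- prob[z, , ]
    sl[r2 <= fz] <- 0.9
    prob[z, , ] <- sl
  }
  truth <- (prob > 0.5) * 1L
  dim(truth) <- d
  list(prob = probability_map(prob, sp), truth = label_volume(truth, sp))
}
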