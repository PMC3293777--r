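#' Pipeline configuration
#'
#' All tunable constants of the three-step pipeline in one validated list.
#' The defaults are the published operating point for 10 nm XY / 50--70 nm Z
#' serial block-face data:
#'
#' * `patch_size` (11): side of the square raw-pixel patch fed to the patch
#'   classifier, in pixels; must be odd.
#' * `iso_levels`: the seven isocontour levels, as fractions of the
#'   probability-map maximum (12%, 26%, ..., 96%, i.e. 14% apart).
#' * `perimeter_min_um`, `perimeter_max_um` (0.6, 6): contours outside this
#'   perimeter range cannot plausibly outline a mitochondrion and are dropped.
#' * `pair_gate_D_um` (0.4): two contours on adjacent planes form a candidate
#'   pair only when their centers are closer than this (strictly).
#' * `contour_set_size_M` (2): classify single contours (1) or pairs (2).
#' * `pair_threshold_T` (0.25): pairs with classifier probability below T are
#'   eliminated.
#' * `erosion_px` (10): in-plane disc erosion of salient-contour interiors
#'   used to produce level-set seeds.
#' * `levelset_advection`, `levelset_curvature`, `levelset_propagation`
#'   (160, 6.75, 1): scalings of the geodesic active contour terms.
#' * `alpha`, `beta` (7, 1): weights of the threshold-selection error
#'   `E = alpha * FPR + beta * (1 - TPR)`.
#' * `duplication_n` (0): each positive contour-pair training example is
#'   duplicated `n` extra times to rebalance classes.
#' * `saliency_fraction` (0.9): a detected contour is a ground-truth positive
#'   when at least this fraction of its interior pixels are labeled.
#' * `threshold_grid`: candidate T values 0.05, 0.10, ..., 1.0.
#' * `n_pos`, `n_neg` (689, 902): training patches sampled per class.
#' * `rf_trees` (100): trees per random forest.
#' * `seed` (1): master RNG seed.
#'
#' @param ... named overrides of the defaults above.
#' @return A validated list of class `mitoseg_config`.
#' @examples
#' cfg <- mitoseg_config(pair_threshold_T = 0.1)
#' cfg$patch_size
#' @export
mitoseg_config <- function(...) {
  defaults <- list(
    patch_size = 11L,
    iso_levels = c(0.12, 0.26, 0.40, 0.54, 0.68, 0.82, 0.96),
    perimeter_min_um = 0.6,
    perimeter_max_um = 6.0,
    pair_gate_D_um = 0.4,
    contour_set_size_M = 2L,
    pair_threshold_T = 0.25,
    erosion_px = 10L,
    levelset_advection = 160,
    levelset_curvature = 6.75,
    levelset_propagation = 1,
    alpha = 7,
    beta = 1,
    duplication_n = 0L,
    saliency_fraction = 0.90,
    threshold_grid = seq(0.05, 1.0, by = 0.05),
    n_pos = 689L,
    n_neg = 902L,
    rf_trees = 100L,
    seed = 1L
  )
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all configuration overrides must be named")
    }
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown) > 0) stop("unknown configuration keys: ",
                                  paste(unknown, collapse = ", "))
    defaults[names(over)] <- over
  }
  validate_config(defaults)
}

validate_config <- function(cfg) {
  int_keys <- c("patch_size", "contour_set_size_M", "erosion_px",
                "duplication_n", "n_pos", "n_neg", "rf_trees", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  num_keys <- setdiff(names(cfg), int_keys)
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])

  if (cfg$patch_size < 3L || cfg$patch_size %% 2L == 0L) {
    stop("patch_size must be an odd integer >= 3")
  }
  lv <- cfg$iso_levels
  if (any(lv <= 0) || any(lv >= 1) || any(diff(lv) <= 0)) {
    stop("iso_levels must be strictly increasing fractions in (0, 1)")
  }
  if (!(cfg$perimeter_min_um > 0 && cfg$perimeter_min_um < cfg$perimeter_max_um)) {
    stop("need 0 < perimeter_min_um < perimeter_max_um")
  }
  if (cfg$pair_threshold_T < 0 || cfg$pair_threshold_T > 1) {
    stop("pair_threshold_T must lie in [0, 1]")
  }
  if (!cfg$contour_set_size_M %in% c(1L, 2L)) {
    stop("contour_set_size_M must be 1 or 2")
  }
  if (cfg$pair_gate_D_um <= 0) stop("pair_gate_D_um must be positive")
  if (cfg$erosion_px < 0) stop("erosion_px must be nonnegative")
  if (cfg$levelset_advection < 0 || cfg$levelset_curvature < 0 ||
      cfg$levelset_propagation < 0) {
    stop("level-set scalings must be nonnegative")
  }
  if (cfg$duplication_n < 0L) stop("duplication_n must be nonnegative")
  if (cfg$saliency_fraction <= 0 || cfg$saliency_fraction > 1) {
    stop("saliency_fraction must lie in (0, 1]")
  }
  if (cfg$rf_trees < 1L) stop("rf_trees must be >= 1")
  structure(cfg, class = "mitoseg_config")
}

#' Load a pipeline configuration file
#'
#' Reads a flat key-value YAML document; keys absent from the file keep their
#' defaults (see [mitoseg_config()]).  Any invariant violation (even patch
#' size, non-increasing iso levels, ...) is rejected with a descriptive
#' error.
#'
#' @param path path to a YAML file; an empty file yields the full defaults.
#' @return A validated `mitoseg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a flat key-value document")
  do.call(mitoseg_config, vals)
}

#' @export
print.mitoseg_config <- function(x, ...) {
  cat("<mitoseg_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k,
                if (length(v) > 4) paste0(paste(head(v, 4), collapse = ", "), ", ...")
                else paste(v, collapse = ", ")))
  }
  invisible(x)
}
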