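#' Volume containers
#'
#' Image stacks are stored as plain 3D arrays in `(z, y, x)` order with a
#' `spacing` attribute giving the physical voxel size in nanometers, also in
#' `(z, y, x)` order.  Three thin classes share this layout:
#' `intensity_volume` (gray values, typically 8-bit integers in 0--255),
#' `label_volume` (binary 0/1 masks) and `probability_map` (reals in
#' \[0, 1\]).  Spacing may be anisotropic; serial block-face stacks typically
#' have a Z step 5--7 times the XY pixel pitch (e.g. 50 nm vs 10 nm).
#'
#' @param data 3D numeric array in `(z, y, x)` order.
#' @param spacing numeric length-3, physical voxel size `(z, y, x)` in nm.
#' @return An array of class `intensity_volume`, `label_volume` or
#'   `probability_map` with a `spacing` attribute.
#' @examples
#' v <- intensity_volume(array(100L, c(2, 4, 4)), spacing = c(50, 10, 10))
#' dim(v)
#' spacing(v)
#' @name volumes
NULL

new_volume <- function(data, spacing, class) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (z, y, x) in nm")
  }
  structure(data, spacing = spacing, class = c(class, "mitoseg_volume"))
}

#' @rdname volumes
#' @export
intensity_volume <- function(data, spacing) {
  new_volume(data, spacing, "intensity_volume")
}

#' @rdname volumes
#' @export
label_volume <- function(data, spacing) {
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1))) stop("label data must be binary 0/1")
  new_volume(data, spacing, "label_volume")
}

#' @rdname volumes
#' @export
probability_map <- function(data, spacing) {
  r <- range(data)
  if (r[1] < 0 || r[2] > 1) stop("probabilities must lie in [0, 1]")
  new_volume(data, spacing, "probability_map")
}

#' @rdname volumes
#' @param x a volume object.
#' @export
spacing <- function(x) attr(x, "spacing")

#' @export
print.mitoseg_volume <- function(x, ...) {
  d <- dim(x)
  sp <- spacing(x)
  cat(sprintf("<%s> %d x %d x %d voxels (z, y, x), spacing %g x %g x %g nm\n",
              class(x)[1], d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  cat(sprintf("  value range [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

# Extract XY slice z as a (y, x) matrix.
slice_of <- function(vol, z) {
  m <- vol[z, , , drop = TRUE]
  dim(m) <- dim(vol)[2:3]
  m
}

check_aligned <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("volumes are not aligned: shapes ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
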