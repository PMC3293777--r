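#' Read an image stack from disk
#'
#' Reads either a multipage TIFF file or a directory of equally sized
#' single-slice PNG/TIFF images.  Directory slices are ordered by ascending
#' lexicographic filename, which is taken to be ascending Z.  8-bit pixel
#' values are preserved exactly (0--255).  Files written by [write_stack()]
#' round-trip bit-exactly.
#'
#' @param path a multipage TIFF file or a directory of slice images.
#' @param spacing physical voxel size `(z, y, x)` in nm.
#' @param labels if `TRUE`, re-binarize the values (on disk labels are
#'   0/255) and return a [label_volume()].
#' @return An [intensity_volume()] (or [label_volume()]) of shape
#'   `(n_slices, height, width)`.
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, spacing = c(50, 10, 10), labels = FALSE) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L) stop("no PNG/TIFF slices found in ", path)
    files <- files[order(basename(files), method = "radix")]
    slices <- lapply(files, read_slice)
  } else {
    slices <- read_multipage_tiff(path)
  }
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("inconsistent slice dimensions across the stack")
  }
  vol <- array(0L, c(length(slices), dims[1, 1], dims[2, 1]))
  for (z in seq_along(slices)) vol[z, , ] <- slices[[z]]
  if (labels) {
    label_volume((vol > 127) * 1L, spacing)
  } else {
    intensity_volume(vol, spacing)
  }
}

read_slice <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "png") {
    m <- png::readPNG(file)
  } else if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(file)
  } else {
    stop("unsupported image format: ", file)
  }
  to_gray_int(m, file)
}

read_multipage_tiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, to_gray_int, file = file)
}

# readTIFF/readPNG return values scaled to [0,1]; recover 8-bit integers.
to_gray_int <- function(m, file) {
  if (length(dim(m)) == 3L) m <- m[, , 1]  # first channel of RGB(A)
  if (max(m) > 1 + 1e-9) stop("unsupported bit depth in ", file)
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write an image stack to disk
#'
#' Writes a volume either as a multipage TIFF (when `path` ends in
#' `.tif`/`.tiff`) or as a directory of per-slice PNGs named
#' `slice_0001.png`, ...  Label volumes are stored as 8-bit 0/255 for viewer
#' compatibility.
#'
#' @param volume an [intensity_volume()] or [label_volume()] (8-bit range).
#' @param path destination file or directory.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path) {
  v <- unclass(volume)
  if (inherits(volume, "label_volume")) v <- v * 255L
  if (min(v) < 0 || max(v) > 255) stop("only 8-bit (0-255) volumes can be written")
  nz <- dim(v)[1]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    pages <- lapply(seq_len(nz), function(z) {
      m <- v[z, , , drop = TRUE]
      dim(m) <- dim(v)[2:3]
      m / 255
    })
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (z in seq_len(nz)) {
      m <- v[z, , , drop = TRUE]
      dim(m) <- dim(v)[2:3]
      png::writePNG(m / 255, file.path(path, sprintf("slice_%04d.png", z)))
    }
  }
  invisible(path)
}
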