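#' Pixel grid: a 2-D intensity image with a physical pixel size
#'
#' The carrier object for every image operation in the package. Values are
#' stored as a numeric matrix in row/column order, where row `i`, column `j`
#' (1-based in R) corresponds to the pixel whose centre sits at physical
#' coordinates `x = (j - 1) * pixel_size_um`, `y = (i - 1) * pixel_size_um`.
#'
#' @param values Numeric matrix of non-negative intensities, at most
#'   `2^bit_depth - 1`.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param bit_depth Integer, 8 or 16. Determines the valid intensity range and
#'   the scale on which fixed thresholds are interpreted.
#' @return An object of class `pixel_grid`.
#' @export
#' @examples
#' g <- pixel_grid(matrix(0, 16, 16), pixel_size_um = 0.65)
#' dim(g$values)
pixel_grid <- function(values, pixel_size_um, bit_depth = 16L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort("`values` must have at least one row and one column.")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.")
  }
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) {
    abort("`bit_depth` must be 8 or 16.")
  }
  vmax <- 2^bit_depth - 1
  if (anyNA(values) || min(values) < 0 || max(values) > vmax) {
    abort(sprintf("`values` must lie in [0, %d] with no missing values.", vmax))
  }
  structure(
    list(values = values, pixel_size_um = pixel_size_um, bit_depth = bit_depth),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf(
    "<pixel_grid> %d x %d px, %.3g um/px, %d-bit, range [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$pixel_size_um, x$bit_depth,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
dim.pixel_grid <- function(x) dim(x$values)

is_pixel_grid <- function(x) inherits(x, "pixel_grid")

#' Read a single-plane grayscale TIFF as a pixel grid
#'
#' @param path Path to an 8- or 16-bit single-plane grayscale TIFF.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return A [pixel_grid()].
#' @export
read_pixel_grid <- function(path, pixel_size_um) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'.", path))
  }
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(planes) != 1L) {
    abort(sprintf(
      "'%s' holds %d planes; expected a single-plane grayscale TIFF.",
      path, length(planes)
    ))
  }
  m <- planes[[1L]]
  if (length(dim(m)) == 3L) {
    abort(sprintf(
      "'%s' has %d channels; extract a single grayscale channel before loading.",
      path, dim(m)[3L]
    ))
  }
  bit_depth <- if (max(m) > 255 || isTRUE(attr(m, "bits.per.sample") == 16L)) 16L else 8L
  storage.mode(m) <- "double"
  pixel_grid(m, pixel_size_um = pixel_size_um, bit_depth = bit_depth)
}

#' Write a pixel grid to a single-plane grayscale TIFF
#'
#' Values are stored at the grid's native bit depth; values beyond the range
#' are clipped with a warning reporting the count.
#'
#' @param grid A [pixel_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pixel_grid <- function(grid, path) {
  stopifnot(is_pixel_grid(grid))
  vmax <- 2^grid$bit_depth - 1
  v <- round(grid$values)
  n_clip <- sum(v < 0 | v > vmax)
  if (n_clip > 0L) {
    warn(sprintf("%d pixel(s) clipped to the %d-bit range on write.",
                 n_clip, grid$bit_depth))
    v <- pmin(pmax(v, 0), vmax)
  }
  tiff::writeTIFF(v / vmax, path, bits.per.sample = grid$bit_depth)
  invisible(path)
}

#' Pair of registered reporter and marker channel images
#'
#' @param reporter,marker [pixel_grid()]s of identical dimensions and pixel
#'   size. The reporter channel carries the droplet-filling spiked reporter
#'   (e.g. mScarlet); the marker channel carries the condensate marker
#'   (e.g. YFP-G3BP1).
#' @return An object of class `channel_pair`.
#' @export
channel_pair <- function(reporter, marker) {
  stopifnot(is_pixel_grid(reporter), is_pixel_grid(marker))
  if (!identical(dim(reporter$values), dim(marker$values))) {
    abort(sprintf(
      "Channel dimensions differ: reporter %dx%d vs marker %dx%d.",
      nrow(reporter$values), ncol(reporter$values),
      nrow(marker$values), ncol(marker$values)
    ))
  }
  if (!identical(reporter$pixel_size_um, marker$pixel_size_um)) {
    abort("Channels must share the same pixel size.")
  }
  structure(list(reporter = reporter, marker = marker), class = "channel_pair")
}

#' @export
print.channel_pair <- function(x, ...) {
  cat("<channel_pair>\n reporter: ")
  print(x$reporter)
  cat(" marker:   ")
  print(x$marker)
  invisible(x)
}
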