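# Label maps: connected-component labellings with physical pixel size.
# Labels are consecutive integers 1..K assigned in row-major (y, x) scan
# order of each object's first pixel; 0 is background.

#' Construct a label map
#'
#' @param labels Integer matrix; 0 = background, k > 0 = object k. Labels are
#'   expected to be consecutive from 1; use [relabel_consecutive()] to fix
#'   gaps.
#' @param pixel_size_um Physical pixel size (um).
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size_um) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix.")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) abort("Labels must be non-negative.")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be > 0.")
  }
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %.3g um/px, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              n_labels(x)))
  invisible(x)
}

#' Number of objects in a label map
#' @param x A [label_map()].
#' @return Integer count of distinct positive labels.
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "label_map"))
  length(setdiff(unique(as.integer(x$labels)), 0L))
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so
# 4-connected components whose pixels touch diagonally are merged with a
# union-find pass, then relabeled in scan order.
label_components_8 <- function(mask) {
  L <- EBImage::imageData(EBImage::bwlabel(1 * (mask > 0)))
  storage.mode(L) <- "integer"
  K <- max(L)
  if (K > 1L) {
    nr <- nrow(L); nc <- ncol(L)
    pairs <- rbind(
      cbind(as.integer(L[-nr, -nc]), as.integer(L[-1, -1])),   # down-right
      cbind(as.integer(L[-nr, -1]), as.integer(L[-1, -nc]))    # down-left
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs) > 0L) {
      parent <- seq_len(K)
      find <- function(a) {
        while (parent[a] != a) {
          parent[a] <<- parent[parent[a]]
          a <- parent[a]
        }
        a
      }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(K), find, integer(1))
      lut <- c(0L, root)
      L[] <- lut[L + 1L]
    }
  }
  relabel_scan_order(L)
}

# Relabel positive labels consecutively 1..K ordered by each object's first
# pixel in row-major (y, x) scan order.
relabel_scan_order <- function(L) {
  ids <- setdiff(sort(unique(as.integer(L))), 0L)
  if (length(ids) == 0L) return(L)
  nr <- nrow(L); nc <- ncol(L)
  idx <- which(L > 0L)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  scan <- (rows - 1L) * nc + (cols - 1L)  # row-major position
  first <- tapply(scan, as.integer(L[idx]), min)
  ord <- as.integer(names(first))[order(first)]
  lut <- integer(max(ids) + 1L)
  lut[ord + 1L] <- seq_along(ord)
  L[] <- lut[L + 1L]
  L
}

#' Relabel a label map so labels are consecutive 1..K
#'
#' Objects are numbered by the scan-order position (row-major) of their first
#' pixel.
#'
#' @param x A [label_map()].
#' @return A [label_map()] with consecutive labels.
#' @export
relabel_consecutive <- function(x) {
  stopifnot(inherits(x, "label_map"))
  label_map(relabel_scan_order(x$labels), x$pixel_size_um)
}

#' Write a label map to a 16-bit TIFF
#'
#' @param x A [label_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(x, path) {
  stopifnot(inherits(x, "label_map"))
  if (max(x$labels) > 65535L) abort("More than 65535 labels; cannot store as 16-bit.")
  tiff::writeTIFF(x$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
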