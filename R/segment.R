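# Two-channel segmentation: droplets ("mothers") on the reporter channel,
# condensates ("children") on the marker channel, and parent assignment.

#' Segmentation parameters
#'
#' @param droplet_gaussian_sigma_px Gaussian pre-filter sigma for the
#'   reporter channel (px, >= 0; 0 disables).
#' @param droplet_threshold `"auto"` for Otsu's threshold, or a fixed
#'   intensity in the reporter grid's native units.
#' @param droplet_min_area_um2 Minimum droplet area kept (um^2).
#' @param exclude_border Drop droplets touching the image border (they are
#'   truncated and would bias area fractions).
#' @param condensate_denoise_radius_px Median-filter radius for the marker
#'   channel (px, >= 0; 0 disables). An edge-preserving denoiser standing in
#'   for learned denoising.
#' @param rolling_ball_radius_px Radius of the rolling-ball background
#'   subtraction on the marker channel (px, >= 1).
#' @param condensate_threshold Fixed condensate intensity threshold,
#'   interpreted on an 8-bit-equivalent scale (default 60) and linearly
#'   rescaled for 16-bit input so conditions stay comparable across inputs.
#' @param condensate_min_area_px Minimum condensate area kept (px).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(droplet_gaussian_sigma_px = 2,
                                droplet_threshold = "auto",
                                droplet_min_area_um2 = 20,
                                exclude_border = TRUE,
                                condensate_denoise_radius_px = 2L,
                                rolling_ball_radius_px = 50L,
                                condensate_threshold = 60,
                                condensate_min_area_px = 5L) {
  if (droplet_gaussian_sigma_px < 0) abort("`droplet_gaussian_sigma_px` must be >= 0.")
  if (!identical(droplet_threshold, "auto") &&
      (!is.numeric(droplet_threshold) || droplet_threshold < 0)) {
    abort("`droplet_threshold` must be \"auto\" or a non-negative intensity.")
  }
  if (droplet_min_area_um2 < 0) abort("`droplet_min_area_um2` must be >= 0.")
  if (condensate_denoise_radius_px < 0) abort("`condensate_denoise_radius_px` must be >= 0.")
  if (rolling_ball_radius_px < 1) abort("`rolling_ball_radius_px` must be >= 1.")
  if (!is.numeric(condensate_threshold) || condensate_threshold < 0 ||
      condensate_threshold > 255) {
    abort("`condensate_threshold` must lie in [0, 255] (8-bit-equivalent scale).")
  }
  if (condensate_min_area_px < 0) abort("`condensate_min_area_px` must be >= 0.")
  structure(
    list(
      droplet_gaussian_sigma_px = droplet_gaussian_sigma_px,
      droplet_threshold = droplet_threshold,
      droplet_min_area_um2 = droplet_min_area_um2,
      exclude_border = isTRUE(exclude_border),
      condensate_denoise_radius_px = as.integer(condensate_denoise_radius_px),
      rolling_ball_radius_px = as.integer(rolling_ball_radius_px),
      condensate_threshold = condensate_threshold,
      condensate_min_area_px = as.integer(condensate_min_area_px)
    ),
    class = "segmentation_params"
  )
}

disc_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  d <- -r:r
  1 * (outer(d^2, d^2, "+") <= radius_px^2)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' image by a disc structuring element of the given radius and subtracts it.
#' Structures narrower than the ball are preserved; anything wider (droplet
#' fill, shading) is removed. Output is non-negative everywhere and never
#' exceeds the input.
#'
#' @param grid A [pixel_grid()].
#' @param radius_px Ball radius in pixels (>= 1, smaller than the image).
#' @return A [pixel_grid()] of the background-subtracted image.
#' @export
subtract_background_rolling_ball <- function(grid, radius_px) {
  stopifnot(is_pixel_grid(grid))
  if (radius_px < 1) abort("`radius_px` must be >= 1.")
  if (2 * radius_px + 1 > min(dim(grid$values))) {
    abort(sprintf(
      "Rolling-ball radius %d exceeds the image extent (%d x %d).",
      radius_px, nrow(grid$values), ncol(grid$values)
    ))
  }
  vmax <- 2^grid$bit_depth - 1
  k <- disc_kernel(radius_px)
  # EBImage grayscale morphology is exact only on [0, 1]; scale, open, rescale
  v01 <- grid$values / vmax
  opened <- EBImage::imageData(EBImage::dilate(EBImage::erode(v01, k), k))
  out <- (v01 - opened) * vmax
  out[out < 0] <- 0  # guard against float round-off
  pixel_grid(out, grid$pixel_size_um, grid$bit_depth)
}

check_threshold <- function(thr, grid) {
  vmax <- 2^grid$bit_depth - 1
  if (thr < 0 || thr > vmax) {
    abort(sprintf("Threshold %g outside the grid's intensity range [0, %d].",
                  thr, vmax))
  }
  thr
}

#' Segment droplets on the reporter channel
#'
#' Gaussian smoothing, intensity threshold (fixed, or Otsu when
#' `droplet_threshold = "auto"`), hole filling, 8-connected component
#' labeling, then removal of components below `droplet_min_area_um2` and
#' (optionally) components touching the image border. Labels are consecutive
#' in scan order.
#'
#' @param reporter A [pixel_grid()] of the droplet-filling reporter channel.
#' @param params A [segmentation_params()].
#' @return A [label_map()] of droplets.
#' @export
segment_droplets <- function(reporter, params = segmentation_params()) {
  stopifnot(is_pixel_grid(reporter), inherits(params, "segmentation_params"))
  vmax <- 2^reporter$bit_depth - 1
  v <- reporter$values
  if (params$droplet_gaussian_sigma_px > 0) {
    v <- EBImage::imageData(EBImage::gblur(v, sigma = params$droplet_gaussian_sigma_px))
  }
  if (identical(params$droplet_threshold, "auto")) {
    thr <- vmax * EBImage::otsu(EBImage::Image(v / vmax), range = c(0, 1),
                                levels = 2^reporter$bit_depth)
    # Otsu splits even a pure-noise image in half; require genuine bimodal
    # separation between the classes before accepting the auto threshold
    fg <- v >= thr
    sd_bg <- sd(v[!fg])
    if (!any(fg) || all(fg) ||
        (mean(v[fg]) - mean(v[!fg])) < 4 * max(sd_bg, .Machine$double.eps)) {
      return(label_map(matrix(0L, nrow(v), ncol(v)), reporter$pixel_size_um))
    }
  } else {
    thr <- check_threshold(params$droplet_threshold, reporter)
  }
  mask <- v >= thr
  mask <- EBImage::imageData(EBImage::fillHull(1 * mask)) > 0
  L <- label_components_8(mask)
  L <- filter_labels(L, min_area_px = params$droplet_min_area_um2 / reporter$pixel_size_um^2,
                     exclude_border = params$exclude_border)
  label_map(L, reporter$pixel_size_um)
}

#' Segment condensates on the marker channel
#'
#' Median-filter denoising, rolling-ball background subtraction, a fixed
#' intensity threshold (8-bit-equivalent scale, rescaled for 16-bit data),
#' 8-connected labeling, and a minimum-area filter. No hole filling:
#' condensates may be thin or irregular.
#'
#' @param marker A [pixel_grid()] of the condensate marker channel.
#' @param params A [segmentation_params()].
#' @return A [label_map()] of condensates.
#' @export
segment_condensates <- function(marker, params = segmentation_params()) {
  stopifnot(is_pixel_grid(marker), inherits(params, "segmentation_params"))
  vmax <- 2^marker$bit_depth - 1
  v <- marker$values
  if (params$condensate_denoise_radius_px > 0) {
    v <- vmax * EBImage::imageData(
      EBImage::medianFilter(v / vmax, params$condensate_denoise_radius_px)
    )
  }
  g <- pixel_grid(pmin(pmax(v, 0), vmax), marker$pixel_size_um, marker$bit_depth)
  g <- subtract_background_rolling_ball(g, params$rolling_ball_radius_px)
  thr <- params$condensate_threshold * if (marker$bit_depth == 16L) 257 else 1
  thr <- check_threshold(thr, marker)
  mask <- g$values >= thr
  L <- label_components_8(mask)
  L <- filter_labels(L, min_area_px = params$condensate_min_area_px,
                     exclude_border = FALSE)
  label_map(L, marker$pixel_size_um)
}

filter_labels <- function(L, min_area_px = 0, exclude_border = FALSE) {
  K <- max(L)
  if (K == 0L) return(L)
  drop <- integer(0)
  if (min_area_px > 0) {
    areas <- tabulate(L[L > 0L], nbins = K)
    drop <- which(areas < min_area_px)
  }
  if (exclude_border) {
    border <- unique(c(L[1, ], L[nrow(L), ], L[, 1], L[, ncol(L)]))
    drop <- union(drop, setdiff(border, 0L))
  }
  if (length(drop) > 0L) {
    lut <- c(0L, seq_len(K))
    lut[drop + 1L] <- 0L
    L[] <- lut[L + 1L]
  }
  relabel_scan_order(L)
}

#' Assign condensates to their parent droplets (mother-child)
#'
#' Each condensate is attributed to the droplet label found under its
#' intensity-unweighted centroid pixel. If the centroid pixel is background,
#' the droplet with the largest pixel overlap wins (smallest label on ties);
#' a condensate overlapping no droplet is an orphan (`parent_label = NA`).
#'
#' @param droplet_labels,condensate_labels [label_map()]s sharing dimensions
#'   and pixel size.
#' @return A tibble with one row per condensate label: `condensate_label`,
#'   `parent_label` (integer or `NA` for orphans), `method`
#'   (`"centroid"`, `"overlap"`, or `"orphan"`).
#' @export
assign_condensates <- function(droplet_labels, condensate_labels) {
  stopifnot(inherits(droplet_labels, "label_map"),
            inherits(condensate_labels, "label_map"))
  if (!identical(dim(droplet_labels$labels), dim(condensate_labels$labels))) {
    abort(sprintf(
      "Label map dimensions differ: droplets %dx%d vs condensates %dx%d.",
      nrow(droplet_labels$labels), ncol(droplet_labels$labels),
      nrow(condensate_labels$labels), ncol(condensate_labels$labels)
    ))
  }
  D <- droplet_labels$labels
  C <- condensate_labels$labels
  K <- max(C)
  if (K == 0L) {
    return(tibble(condensate_label = integer(), parent_label = integer(),
                  method = character()))
  }
  nr <- nrow(C)
  idx <- which(C > 0L)
  lab <- C[idx]
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  out <- purrr::map_dfr(seq_len(K), function(k) {
    sel <- lab == k
    r <- rows[sel]; cc <- cols[sel]
    ci <- round(mean(r)); cj <- round(mean(cc))
    parent <- NA_integer_; method <- "orphan"
    if (ci >= 1 && ci <= nr && cj >= 1 && cj <= ncol(C) && D[ci, cj] > 0L) {
      parent <- D[ci, cj]
      method <- "centroid"
    } else {
      under <- D[cbind(r, cc)]
      under <- under[under > 0L]
      if (length(under) > 0L) {
        counts <- table(under)
        best <- as.integer(names(counts)[counts == max(counts)])
        parent <- min(best)
        method <- "overlap"
      }
    }
    tibble(condensate_label = k, parent_label = parent, method = method)
  })
  out
}
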