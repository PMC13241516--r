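# Synthetic two-channel emulsion micrograph generator with ground truth.
# Coordinates: pixel (row i, col j), 1-based in R, has its centre at
# x = (j-1)*px, y = (i-1)*px um. Ground truth is continuous (um).

BACKGROUND_LEVEL <- 200       # camera offset, a.u. on the 16-bit scale
MARKER_FILL_FRACTION <- 0.1   # dim marker-channel droplet fill, fraction of reporter fill
DROPLET_MIN_GAP_UM <- 2       # enforced clearance between droplet rims

#' Sample non-overlapping droplet ground truth
#'
#' Places `config$n_droplets` circular droplets fully inside the image by
#' rejection sampling. Diameters are log-normal with parameters
#' `diam_log_mu`, `diam_log_sigma` (um); the distribution's median diameter is
#' `exp(diam_log_mu)`. Each droplet receives a reporter fill intensity
#' `intensity_base + intensity_diameter_slope * diameter` plus Gaussian
#' jitter (sd 5% of `intensity_base`), so mean fill correlates positively
#' with diameter.
#'
#' @param config A [scene_config()].
#' @return A tibble with one row per droplet: `droplet_id`, `center_x_um`,
#'   `center_y_um`, `radius_um`, `fill_intensity`.
#' @export
#' @examples
#' d <- sample_droplets(scene_config(n_droplets = 5, rng_seed = 3))
#' nrow(d)
sample_droplets <- function(config) {
  config <- validate_scene_config(config)
  n <- config$n_droplets
  if (n == 0L) {
    return(tibble(
      droplet_id = integer(), center_x_um = double(), center_y_um = double(),
      radius_um = double(), fill_intensity = double()
    ))
  }
  px <- config$pixel_size_um
  w_um <- (config$image_width_px - 1) * px
  h_um <- (config$image_height_px - 1) * px
  withr::with_seed(config$rng_seed, {
    diam <- rlnorm(n, config$diam_log_mu, config$diam_log_sigma)
    # place the largest first: better packing, same accepted set for a seed
    ord <- order(diam, decreasing = TRUE)
    r <- diam[ord] / 2
    jitter_sd <- 0.05 * config$intensity_base
    fill <- config$intensity_base + config$intensity_diameter_slope * diam[ord] +
      rnorm(n, 0, jitter_sd)
    fill <- pmax(fill, 0)
    cx <- cy <- numeric(n)
    placed <- 0L
    budget <- 200L * n
    attempts <- 0L
    margin <- px  # keep rims one pixel clear of the border
    while (placed < n && attempts < budget) {
      attempts <- attempts + 1L
      i <- placed + 1L
      lo_x <- r[i] + margin; hi_x <- w_um - r[i] - margin
      lo_y <- r[i] + margin; hi_y <- h_um - r[i] - margin
      if (hi_x <= lo_x || hi_y <= lo_y) next  # droplet larger than the field
      x <- runif(1, lo_x, hi_x)
      y <- runif(1, lo_y, hi_y)
      ok <- placed == 0L ||
        all(sqrt((cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2) >=
              r[seq_len(placed)] + r[i] + DROPLET_MIN_GAP_UM)
      if (ok) {
        placed <- i
        cx[i] <- x; cy[i] <- y
      }
    }
    if (placed < n) {
      abort(sprintf(
        "scene too crowded: placed %d of %d droplets within the retry budget.",
        placed, n
      ))
    }
    tibble(
      droplet_id = seq_len(n),
      center_x_um = cx,
      center_y_um = cy,
      radius_um = r,
      fill_intensity = fill
    )
  })
}

# Irregular star-shaped condensate outline: radius rho(theta) = 1 + sum of
# low-order harmonics, scaled so the polygon arc length hits a target
# perimeter. Amplitudes are tuned so the analytic circularity of generated
# shapes falls mostly in 0.4-0.8 (condensates are visibly less circular than
# stress granules in cells).
condensate_shape <- function(target_perimeter_um, n_theta = 720L) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  harmonics <- 2:6
  amp <- runif(length(harmonics), 0, 1 / harmonics)
  phase <- runif(length(harmonics), 0, 2 * pi)
  rho <- 1 + colSums(amp * cos(outer(harmonics, theta) + phase))
  rho <- pmax(rho, 0.35)
  # arc length of the unit polygon, then linear scale to the target
  xs <- rho * cos(theta); ys <- rho * sin(theta)
  seg <- sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2)
  unit_len <- sum(seg)
  r0 <- target_perimeter_um / unit_len
  area <- r0^2 * abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  list(
    theta = theta, rho = rho, r0 = r0,
    r_max = r0 * max(rho),
    perimeter_um = target_perimeter_um,
    area_um2 = area,
    amp = amp, phase = phase, harmonics = harmonics
  )
}

shape_radius_at <- function(shape, theta) {
  shape$r0 * pmax(
    1 + colSums(shape$amp * cos(outer(shape$harmonics, theta) + shape$phase)),
    0.35
  )
}

rasterize_shape <- function(shape, cx_um, cy_um, config) {
  px <- config$pixel_size_um
  r_max <- shape$r_max
  j_lo <- max(1L, floor((cx_um - r_max) / px) + 1L)
  j_hi <- min(config$image_width_px, ceiling((cx_um + r_max) / px) + 1L)
  i_lo <- max(1L, floor((cy_um - r_max) / px) + 1L)
  i_hi <- min(config$image_height_px, ceiling((cy_um + r_max) / px) + 1L)
  if (j_hi < j_lo || i_hi < i_lo) return(NULL)
  jj <- j_lo:j_hi; ii <- i_lo:i_hi
  xg <- (rep(jj, each = length(ii)) - 1) * px - cx_um
  yg <- (rep(ii, times = length(jj)) - 1) * px - cy_um
  d <- sqrt(xg^2 + yg^2)
  th <- atan2(yg, xg)
  inside <- d <= shape_radius_at(shape, th)
  if (!any(inside)) return(NULL)
  cbind(
    row = rep(ii, times = length(jj))[inside],
    col = rep(jj, each = length(ii))[inside]
  )
}

#' Inject irregular condensates into droplets
#'
#' Each droplet independently becomes condensate-positive with probability
#' `condensate_prob`; positive droplets receive `1 + Poisson` condensates
#' whose target perimeters are drawn uniformly from
#' `condensate_perimeter_range_um`. Shapes are radial-perturbation polygons
#' rasterized strictly inside the parent disc; a condensate that cannot fit
#' is shrunk, and skipped with a warning if still too large.
#'
#' @param droplets Droplet ground truth from [sample_droplets()].
#' @param config The [scene_config()] used to generate `droplets`.
#' @return A tibble with one row per condensate: `condensate_id`,
#'   `parent_droplet_id`, `area_um2`, `perimeter_um`, and a `pixel_mask`
#'   list-column of (row, col) pixel coordinate matrices.
#' @export
inject_condensates <- function(droplets, config) {
  config <- validate_scene_config(config)
  empty <- tibble(
    condensate_id = integer(), parent_droplet_id = integer(),
    area_um2 = double(), perimeter_um = double(), pixel_mask = list()
  )
  if (nrow(droplets) == 0L || config$condensate_prob == 0) return(empty)
  prange <- config$condensate_perimeter_range_um
  withr::with_seed(config$rng_seed + 1L, {
    rows <- list()
    margin <- config$pixel_size_um
    for (i in seq_len(nrow(droplets))) {
      if (runif(1) > config$condensate_prob) next
      n_c <- 1L + rpois(1L, config$condensates_per_droplet_mean - 1)
      placed_centers <- NULL
      for (k in seq_len(n_c)) {
        target <- runif(1, prange[1], prange[2])
        shape <- condensate_shape(target)
        R <- droplets$radius_um[i]
        if (shape$r_max + margin > R) {
          # shrink to fit; skip if degenerate
          scl <- 0.9 * (R - margin) / shape$r_max
          if (scl <= 0 || shape$perimeter_um * scl < 3) {
            warn(sprintf(
              "condensate skipped: droplet %d (radius %.1f um) too small for target perimeter %.1f um.",
              droplets$droplet_id[i], R, target
            ))
            next
          }
          shape$r0 <- shape$r0 * scl
          shape$r_max <- shape$r_max * scl
          shape$perimeter_um <- shape$perimeter_um * scl
          shape$area_um2 <- shape$area_um2 * scl^2
        }
        ok <- FALSE
        for (try in 1:20) {
          d_max <- R - shape$r_max - margin
          d <- sqrt(runif(1)) * max(d_max, 0)
          ang <- runif(1, 0, 2 * pi)
          cx <- droplets$center_x_um[i] + d * cos(ang)
          cy <- droplets$center_y_um[i] + d * sin(ang)
          if (is.null(placed_centers) ||
              all(sqrt((placed_centers[, 1] - cx)^2 + (placed_centers[, 2] - cy)^2) >=
                    shape$r_max + placed_centers[, 3])) {
            ok <- TRUE
            break
          }
        }
        if (!ok) next  # no room for a sibling; drop silently
        mask <- rasterize_shape(shape, cx, cy, config)
        if (is.null(mask)) next
        placed_centers <- rbind(placed_centers, c(cx, cy, shape$r_max))
        rows[[length(rows) + 1L]] <- tibble(
          parent_droplet_id = droplets$droplet_id[i],
          area_um2 = shape$area_um2,
          perimeter_um = shape$perimeter_um,
          pixel_mask = list(mask)
        )
      }
    }
    if (length(rows) == 0L) return(empty)
    out <- dplyr::bind_rows(rows)
    dplyr::mutate(out, condensate_id = dplyr::row_number(), .before = 1L)
  })
}

#' Render a ground-truth scene into a two-channel 16-bit image pair
#'
#' The reporter channel is a flat camera background plus each droplet's fill
#' intensity; the marker channel carries a dim droplet fill (10% of the
#' reporter fill) plus bright condensate masks at `condensate_intensity`.
#' Both channels are corrupted by Poisson-scaled shot noise and additive
#' Gaussian read noise, then rounded and clipped to the 16-bit range (clipped
#' pixels are reported via a message).
#'
#' @param droplets Tibble from [sample_droplets()].
#' @param condensates Tibble from [inject_condensates()].
#' @param config The generating [scene_config()].
#' @return A [channel_pair()].
#' @export
render_scene <- function(droplets, condensates, config) {
  config <- validate_scene_config(config)
  h <- config$image_height_px; w <- config$image_width_px
  px <- config$pixel_size_um
  reporter <- matrix(BACKGROUND_LEVEL, h, w)
  marker <- matrix(BACKGROUND_LEVEL, h, w)
  for (i in seq_len(nrow(droplets))) {
    R <- droplets$radius_um[i]
    cx <- droplets$center_x_um[i]; cy <- droplets$center_y_um[i]
    j_lo <- max(1L, floor((cx - R) / px) + 1L)
    j_hi <- min(w, ceiling((cx + R) / px) + 1L)
    i_lo <- max(1L, floor((cy - R) / px) + 1L)
    i_hi <- min(h, ceiling((cy + R) / px) + 1L)
    jj <- j_lo:j_hi; ii <- i_lo:i_hi
    dx <- (jj - 1) * px - cx
    dy <- (ii - 1) * px - cy
    inside <- outer(dy^2, dx^2, "+") <= R^2
    fill <- droplets$fill_intensity[i]
    sub <- reporter[ii, jj, drop = FALSE]
    sub[inside] <- sub[inside] + fill
    reporter[ii, jj] <- sub
    subm <- marker[ii, jj, drop = FALSE]
    subm[inside] <- subm[inside] + MARKER_FILL_FRACTION * fill
    marker[ii, jj] <- subm
  }
  for (k in seq_len(nrow(condensates))) {
    m <- condensates$pixel_mask[[k]]
    marker[m] <- marker[m] + config$condensate_intensity
  }
  withr::with_seed(config$rng_seed + 2L, {
    add_noise <- function(v) {
      shot_sd <- sqrt(pmax(v, 0) * config$noise_poisson_scale)
      v + rnorm(length(v), 0, 1) * shot_sd +
        rnorm(length(v), 0, config$noise_gaussian_sd)
    }
    reporter[] <- add_noise(reporter)
    marker[] <- add_noise(marker)
  })
  clip16 <- function(v, name) {
    n_over <- sum(v > 65535)
    if (n_over > 0L) {
      inform(sprintf("render_scene: %d %s pixel(s) clipped to the 16-bit maximum.",
                     n_over, name))
    }
    # noise below the camera offset clips silently at 0, as on a real sensor
    pmin(pmax(round(v), 0), 65535)
  }
  reporter[] <- clip16(reporter, "reporter")
  marker[] <- clip16(marker, "marker")
  channel_pair(
    reporter = pixel_grid(reporter, px, 16L),
    marker = pixel_grid(marker, px, 16L)
  )
}

#' Simulate one complete scene: droplets, condensates, rendered channels
#'
#' @param config A [scene_config()].
#' @return A list with elements `droplets`, `condensates`, `channels`,
#'   `config`.
#' @export
simulate_scene <- function(config) {
  config <- validate_scene_config(config)
  droplets <- sample_droplets(config)
  condensates <- inject_condensates(droplets, config)
  channels <- render_scene(droplets, condensates, config)
  list(droplets = droplets, condensates = condensates,
       channels = channels, config = config)
}

#' Export a rendered scene and its ground truth to disk
#'
#' Writes one 16-bit grayscale TIFF per channel and two CSV ground-truth
#' tables (one row per droplet, one per condensate). Reading the TIFFs back
#' with [read_pixel_grid()] reproduces the arrays exactly.
#'
#' @param channels A [channel_pair()].
#' @param droplets,condensates Ground-truth tibbles.
#' @param directory Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
export_scene <- function(channels, droplets, condensates, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) {
    abort(sprintf("Cannot create output directory '%s'.", directory))
  }
  paths <- c(
    reporter = file.path(directory, "reporter.tif"),
    marker = file.path(directory, "marker.tif"),
    droplets = file.path(directory, "droplets.csv"),
    condensates = file.path(directory, "condensates.csv")
  )
  write_pixel_grid(channels$reporter, paths[["reporter"]])
  write_pixel_grid(channels$marker, paths[["marker"]])
  n_cond <- if (nrow(condensates)) {
    cnt <- table(condensates$parent_droplet_id)
    as.integer(cnt[as.character(droplets$droplet_id)])
  } else {
    integer(nrow(droplets))
  }
  n_cond[is.na(n_cond)] <- 0L
  dtab <- data.frame(
    id = droplets$droplet_id,
    cx_um = droplets$center_x_um,
    cy_um = droplets$center_y_um,
    radius_um = droplets$radius_um,
    fill_intensity = droplets$fill_intensity,
    n_condensates = n_cond
  )
  write.csv(dtab, paths[["droplets"]], row.names = FALSE)
  ctab <- data.frame(
    id = condensates$condensate_id %||% integer(),
    parent_id = condensates$parent_droplet_id %||% integer(),
    area_um2 = condensates$area_um2 %||% double(),
    perimeter_um = condensates$perimeter_um %||% double()
  )
  if (nrow(condensates) == 0L) {
    ctab <- data.frame(id = integer(), parent_id = integer(),
                       area_um2 = double(), perimeter_um = double())
  }
  write.csv(ctab, paths[["condensates"]], row.names = FALSE)
  invisible(paths)
}
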