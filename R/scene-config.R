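#' Scene configuration for the synthetic micrograph generator
#'
#' Describes one simulated two-channel emulsion micrograph: image geometry,
#' the log-normal droplet-diameter model, the linear fill-intensity model,
#' the stress-dependent condensate load, and the camera noise model. The
#' defaults encode the study conditions the generator emulates: a median
#' droplet diameter of `exp(3.2308)` = 25.3 um with log-sd 0.45, condensate
#' perimeters targeted to the 15-34 um range, and a 16-bit camera.
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param pixel_size_um Physical pixel size, um per pixel.
#' @param n_droplets Number of droplets to place (>= 0).
#' @param diam_log_mu,diam_log_sigma Mean and sd of log diameter (um) for the
#'   log-normal droplet-diameter distribution; the distribution's median is
#'   `exp(diam_log_mu)`.
#' @param intensity_base,intensity_diameter_slope Reporter fill model: the
#'   mean fill of a droplet of diameter d um is
#'   `intensity_base + intensity_diameter_slope * d` (a.u. on the 16-bit
#'   scale), plus per-droplet jitter with sd `0.05 * intensity_base`.
#' @param condensate_prob Probability in \[0, 1\] that a droplet carries at
#'   least one condensate.
#' @param condensates_per_droplet_mean Mean number of condensates in a
#'   condensate-positive droplet (>= 1; the count is 1 plus a Poisson draw).
#' @param condensate_perimeter_range_um Length-2 numeric, the (low, high)
#'   interval from which target condensate perimeters are drawn uniformly.
#' @param condensate_intensity Added marker-channel intensity of condensate
#'   pixels (a.u.).
#' @param noise_gaussian_sd Additive Gaussian read-noise sd (a.u.).
#' @param noise_poisson_scale Scale of the Poisson-like shot noise: a pixel of
#'   mean v receives noise of sd `sqrt(v * noise_poisson_scale)`.
#' @param rng_seed Integer seed; all generator stages derive their streams
#'   from it.
#' @return An object of class `scene_config` (a validated named list).
#' @export
#' @examples
#' cfg <- scene_config(n_droplets = 10, rng_seed = 7)
#' cfg$diam_log_mu
scene_config <- function(image_height_px = 1200L,
                         image_width_px = 1200L,
                         pixel_size_um = 0.65,
                         n_droplets = 120L,
                         diam_log_mu = 3.2308,
                         diam_log_sigma = 0.45,
                         intensity_base = 6000,
                         intensity_diameter_slope = 40,
                         condensate_prob = 0.75,
                         condensates_per_droplet_mean = 1.5,
                         condensate_perimeter_range_um = c(15, 34),
                         condensate_intensity = 30000,
                         noise_gaussian_sd = 120,
                         noise_poisson_scale = 1,
                         rng_seed = 1L) {
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = as.numeric(pixel_size_um),
    n_droplets = as.integer(n_droplets),
    diam_log_mu = as.numeric(diam_log_mu),
    diam_log_sigma = as.numeric(diam_log_sigma),
    intensity_base = as.numeric(intensity_base),
    intensity_diameter_slope = as.numeric(intensity_diameter_slope),
    condensate_prob = as.numeric(condensate_prob),
    condensates_per_droplet_mean = as.numeric(condensates_per_droplet_mean),
    condensate_perimeter_range_um = as.numeric(condensate_perimeter_range_um),
    condensate_intensity = as.numeric(condensate_intensity),
    noise_gaussian_sd = as.numeric(noise_gaussian_sd),
    noise_poisson_scale = as.numeric(noise_poisson_scale),
    rng_seed = as.integer(rng_seed)
  )
  validate_scene_config(cfg)
}

validate_scene_config <- function(cfg) {
  stopifnot(is.list(cfg))
  chk <- function(ok, msg) if (!isTRUE(ok)) abort(paste0("Invalid scene_config: ", msg))
  chk(cfg$image_height_px >= 1L && cfg$image_width_px >= 1L,
      "image dimensions must be positive.")
  chk(cfg$pixel_size_um > 0, "pixel_size_um must be > 0.")
  chk(cfg$n_droplets >= 0L, "n_droplets must be >= 0.")
  chk(cfg$diam_log_sigma >= 0, "diam_log_sigma must be >= 0.")
  chk(cfg$condensate_prob >= 0 && cfg$condensate_prob <= 1,
      "condensate_prob must lie in [0, 1].")
  chk(cfg$condensates_per_droplet_mean >= 1,
      "condensates_per_droplet_mean must be >= 1.")
  chk(length(cfg$condensate_perimeter_range_um) == 2L &&
        cfg$condensate_perimeter_range_um[1] > 0 &&
        diff(cfg$condensate_perimeter_range_um) >= 0,
      "condensate_perimeter_range_um must be a positive (low, high) pair.")
  chk(cfg$condensate_intensity >= 0, "condensate_intensity must be >= 0.")
  chk(cfg$noise_gaussian_sd >= 0 && cfg$noise_poisson_scale >= 0,
      "noise parameters must be >= 0.")
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %dx%d px @ %.3g um/px, %d droplets (median diam %.1f um), condensate prob %.2f, seed %d\n",
    x$image_height_px, x$image_width_px, x$pixel_size_um, x$n_droplets,
    exp(x$diam_log_mu), x$condensate_prob, x$rng_seed
  ))
  invisible(x)
}

#' Write or read a scene configuration as JSON
#'
#' The JSON form round-trips losslessly through [read_scene_config()].
#'
#' @param config A [scene_config()].
#' @param path File path.
#' @return `write_scene_config()` returns `path` invisibly;
#'   `read_scene_config()` returns a `scene_config`.
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scene_config, raw)
}
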