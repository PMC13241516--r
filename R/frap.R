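# FRAP: trace simulation, normalization, and single-exponential recovery
# fitting. The model is I(t) = P - (P - I0) * exp(-k t) for t >= 0 after the
# bleach, with half-time t1/2 = ln(2)/k.

#' Simulate a FRAP recovery trace
#'
#' Produces `n_prebleach` frames at `pre_bleach_level` (negative times), then
#' a single-exponential recovery
#' `I(t) = plateau - (plateau - post_bleach_level) * exp(-rate_k_per_s * t)`
#' sampled every `dt_s` seconds up to `duration_s`, with optional Gaussian
#' noise on the bleach-ROI series. A constant reference-region series at
#' `pre_bleach_level` is included for normalization.
#'
#' @param rate_k_per_s Recovery rate constant k (1/s, >= 0).
#' @param pre_bleach_level,post_bleach_level,plateau Intensities (a.u.).
#' @param dt_s Frame interval (s, > 0).
#' @param duration_s Post-bleach duration (s, >= dt_s).
#' @param noise_sd Gaussian noise sd on the bleach series (>= 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param n_prebleach Number of pre-bleach frames (>= 1).
#' @return A `frap_trace`: a tibble with columns `time_s`, `bleach`,
#'   `reference` and attribute `n_prebleach`. Pre-bleach frames carry
#'   negative times; the first post-bleach frame is at t = 0.
#' @export
#' @examples
#' tr <- simulate_frap_trace(log(2) / 4.8, 100, 20, 90, 0.5, 180)
#' head(tr, 7)
simulate_frap_trace <- function(rate_k_per_s,
                                pre_bleach_level = 100,
                                post_bleach_level = 20,
                                plateau = 90,
                                dt_s = 0.5,
                                duration_s = 180,
                                noise_sd = 0,
                                seed = 1L,
                                n_prebleach = 5L) {
  if (rate_k_per_s < 0) abort("`rate_k_per_s` must be >= 0.")
  if (dt_s <= 0) abort("`dt_s` must be > 0.")
  if (duration_s < dt_s) abort("`duration_s` must be >= `dt_s`.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L) abort("`n_prebleach` must be >= 1.")
  t_pre <- -rev(seq_len(n_prebleach)) * dt_s
  t_post <- seq(0, duration_s, by = dt_s)
  recovery <- plateau - (plateau - post_bleach_level) * exp(-rate_k_per_s * t_post)
  bleach <- c(rep(pre_bleach_level, n_prebleach), recovery)
  if (noise_sd > 0) {
    bleach <- withr::with_seed(seed, bleach + rnorm(length(bleach), 0, noise_sd))
  }
  new_frap_trace(
    tibble(
      time_s = c(t_pre, t_post),
      bleach = bleach,
      reference = rep(pre_bleach_level, n_prebleach + length(t_post))
    ),
    n_prebleach = n_prebleach
  )
}

new_frap_trace <- function(df, n_prebleach) {
  out <- as_tibble(df)
  attr(out, "n_prebleach") <- as.integer(n_prebleach)
  class(out) <- c("frap_trace", class(out))
  out
}

#' Read a FRAP trace from CSV
#'
#' Expects columns `time_s`, `bleach`, `reference`.
#'
#' @param path CSV path.
#' @param n_prebleach Number of leading pre-bleach frames.
#' @return A `frap_trace` tibble.
#' @export
read_frap_trace <- function(path, n_prebleach) {
  df <- read.csv(path)
  need <- c("time_s", "bleach", "reference")
  if (!all(need %in% names(df))) {
    abort(sprintf("FRAP CSV must have columns %s.", paste(need, collapse = ", ")))
  }
  if (n_prebleach < 1L || n_prebleach >= nrow(df)) {
    abort("`n_prebleach` must be >= 1 and smaller than the series length.")
  }
  new_frap_trace(df[need], n_prebleach)
}

#' Normalize a FRAP trace to percent of pre-bleach intensity
#'
#' The bleach-ROI series is divided frame-by-frame by the reference-region
#' series (removing illumination drift), then scaled so the mean over the
#' pre-bleach frames is 100%.
#'
#' @param trace A `frap_trace` (see [simulate_frap_trace()],
#'   [read_frap_trace()]).
#' @return A tibble with columns `time_s`, `intensity_pct`, carrying the
#'   `n_prebleach` attribute.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace") || is.data.frame(trace))
  n_pre <- attr(trace, "n_prebleach")
  if (is.null(n_pre)) abort("`trace` must carry an `n_prebleach` attribute.")
  if (n_pre >= nrow(trace)) abort("`n_prebleach` must be smaller than the series length.")
  bad <- which(trace$reference <= 0)
  if (length(bad) > 0L) {
    abort(sprintf("Non-positive reference intensity at frame %d.", bad[1]))
  }
  r <- trace$bleach / trace$reference
  pre_mean <- mean(r[seq_len(n_pre)])
  if (pre_mean <= 0) abort("Pre-bleach mean must be positive.")
  out <- tibble(time_s = trace$time_s, intensity_pct = 100 * r / pre_mean)
  attr(out, "n_prebleach") <- n_pre
  out
}

#' Half-time of a single-exponential recovery
#'
#' @param rate_k_per_s Rate constant k (1/s, > 0).
#' @return `log(2) / k`, in seconds.
#' @export
#' @examples
#' half_time(log(2))  # 1 s
half_time <- function(rate_k_per_s) {
  if (any(rate_k_per_s <= 0)) abort("`rate_k_per_s` must be > 0.")
  log(2) / rate_k_per_s
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of `I(t) = P - (P - I0) * exp(-k t)` to the post-bleach
#' portion of a normalized trace (times re-zeroed at the first post-bleach
#' frame). Initialization is deterministic from the data: I0 = first
#' post-bleach value, P = mean of the last 10% of frames, k = ln(2) over the
#' time to half range.
#'
#' @param normalized A tibble from [normalize_trace()] (columns `time_s`,
#'   `intensity_pct`, attribute `n_prebleach`), or any data frame with those
#'   columns if `n_prebleach` is given.
#' @param n_prebleach Overrides the trace's `n_prebleach` attribute.
#' @return A `frap_fit` object with elements `rate_k_per_s`, `half_time_s`,
#'   `plateau_pct`, `post_bleach_pct`, `mobile_fraction`,
#'   `residual_sum_squares`, and the fitted curve as a tibble `data`.
#' @export
#' @examples
#' tr <- simulate_frap_trace(log(2) / 4.8)
#' fit <- fit_recovery(normalize_trace(tr))
#' fit$half_time_s
fit_recovery <- function(normalized, n_prebleach = NULL) {
  n_pre <- n_prebleach %||% attr(normalized, "n_prebleach")
  if (is.null(n_pre)) abort("Supply `n_prebleach` or a trace carrying the attribute.")
  t_all <- normalized$time_s
  y_all <- normalized$intensity_pct
  post <- seq.int(n_pre + 1L, length(t_all))
  if (length(post) < 5L) abort("Need at least 5 post-bleach points to fit.")
  t <- t_all[post] - t_all[post[1]]
  y <- y_all[post]
  pre_level <- mean(y_all[seq_len(n_pre)])
  if (min(y) >= pre_level) {
    abort("Post-bleach minimum is not below the pre-bleach level; nothing to fit.")
  }
  i0_init <- y[1]
  p_init <- mean(y[t >= max(t) * 0.9])
  half_level <- i0_init + (p_init - i0_init) / 2
  t_half_idx <- which(y >= half_level)[1]
  k_init <- if (is.na(t_half_idx) || t[t_half_idx] <= 0) {
    log(2) / (max(t) / 4)
  } else {
    log(2) / t[t_half_idx]
  }
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ P - (P - I0) * exp(-k * t),
      data = df,
      start = list(P = p_init, I0 = i0_init, k = k_init),
      lower = c(P = 0, I0 = 0, k = 1e-8),
      upper = c(P = Inf, I0 = Inf, k = 1e4),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      abort(sprintf(
        "FRAP fit failed: %s (starts: P=%.3g, I0=%.3g, k=%.3g).",
        conditionMessage(e), p_init, i0_init, k_init
      ))
    }
  )
  cf <- coef(fit)
  k <- unname(cf["k"])
  if (k <= 2e-8 || k >= 0.99e4) {
    warn(sprintf("Fitted rate k = %.3g 1/s is at the optimization bound.", k))
  }
  rss <- sum(residuals(fit)^2)
  fitted_curve <- tibble(
    time_s = t_all[post],
    intensity_pct = y,
    fitted_pct = unname(predict(fit))
  )
  mob <- (cf["P"] - cf["I0"]) / (100 - cf["I0"])
  structure(
    list(
      rate_k_per_s = k,
      half_time_s = log(2) / k,
      plateau_pct = unname(cf["P"]),
      post_bleach_pct = unname(cf["I0"]),
      mobile_fraction = unname(pmin(pmax(mob, 0), 1)),
      residual_sum_squares = rss,
      n_points = length(y),
      data = fitted_curve
    ),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> k = %.4g 1/s, t1/2 = %.3g s, plateau = %.3g%%, mobile fraction = %.2f (RSS %.3g, n = %d)\n",
    x$rate_k_per_s, x$half_time_s, x$plateau_pct, x$mobile_fraction,
    x$residual_sum_squares, x$n_points
  ))
  invisible(x)
}

#' Tidy a FRAP fit into one row per parameter
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(
    term = c("rate_k_per_s", "half_time_s", "plateau_pct",
             "post_bleach_pct", "mobile_fraction"),
    estimate = c(x$rate_k_per_s, x$half_time_s, x$plateau_pct,
                 x$post_bleach_pct, x$mobile_fraction)
  )
}

#' One-row summary of a FRAP fit
#'
#' @param x A `frap_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(
    half_time_s = x$half_time_s,
    mobile_fraction = x$mobile_fraction,
    residual_sum_squares = x$residual_sum_squares,
    n_points = x$n_points
  )
}

#' Plot a FRAP fit: normalized data with the fitted recovery curve
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frap_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity_pct),
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_pct),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "Time after bleach (s)", y = "Intensity (% of pre-bleach)",
      title = sprintf("FRAP recovery, t1/2 = %.2f s", object$half_time_s)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom stats residuals predict
NULL
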