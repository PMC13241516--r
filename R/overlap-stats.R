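# Light statistics: Pearson line-profile colocalisation and upper-tail
# hypergeometric set-overlap enrichment with Benjamini-Hochberg adjustment.

#' Pearson correlation of a two-channel line profile
#'
#' Sample Pearson correlation R between the two fluorescence-channel
#' intensity series sampled along a drawn line; quantifies colocalisation.
#'
#' @param profile Data frame with columns `positions_um` (strictly
#'   increasing), `intensity_a`, `intensity_b` (equal lengths >= 3).
#' @return R in \[-1, 1\].
#' @export
#' @examples
#' p <- tibble::tibble(positions_um = 1:5, intensity_a = 1:5, intensity_b = 1:5)
#' pearson_line_profile(p)  # 1
pearson_line_profile <- function(profile) {
  need <- c("positions_um", "intensity_a", "intensity_b")
  if (!all(need %in% names(profile))) {
    abort(sprintf("`profile` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (nrow(profile) < 3L) abort("A line profile needs at least 3 samples.")
  if (is.unsorted(profile$positions_um, strictly = TRUE)) {
    abort("`positions_um` must be strictly increasing.")
  }
  if (sd(profile$intensity_a) == 0 || sd(profile$intensity_b) == 0) {
    abort("Pearson correlation is undefined for a constant channel.")
  }
  cor(profile$intensity_a, profile$intensity_b)
}

#' Read a line profile from CSV
#'
#' @param path CSV with columns `positions_um`, `intensity_a`, `intensity_b`.
#' @return A tibble.
#' @export
read_line_profile <- function(path) {
  as_tibble(read.csv(path))
}

#' Hypergeometric set-overlap enrichment
#'
#' Upper-tail (enrichment) test: the probability of observing at least `k`
#' shared identifiers when `n` are drawn without replacement from a universe
#' of `N` containing `K` marked ones. Computed on the log scale internally so
#' gene-scale universes do not underflow. The enrichment factor is observed
#' over expected overlap, `k / (n K / N)`.
#'
#' @param N Universe size.
#' @param K Size of set A.
#' @param n Size of set B (the draw).
#' @param k Observed overlap.
#' @return A one-row tibble: `universe_size`, `set_a_size`, `draw_size`,
#'   `overlap`, `p_value`, `enrichment_factor`.
#' @export
#' @examples
#' hypergeom_overlap(10, 5, 4, 4)$p_value  # 5/210
hypergeom_overlap <- function(N, K, n, k) {
  v <- c(N = N, K = K, n = n, k = k)
  if (any(v != round(v)) || any(v < 0)) {
    abort("N, K, n, k must be non-negative integers.")
  }
  if (K > N || n > N) abort("K and n must not exceed N.")
  if (k > min(K, n)) abort("k must not exceed min(K, n).")
  # upper tail P(X >= k), evaluated stably on the log scale
  p <- if (k == 0) 1 else exp(stats::phyper(k - 1, K, N - K, n,
                                            lower.tail = FALSE, log.p = TRUE))
  expected <- n * K / N
  tibble(
    universe_size = as.integer(N),
    set_a_size = as.integer(K),
    draw_size = as.integer(n),
    overlap = as.integer(k),
    p_value = min(p, 1),
    enrichment_factor = if (expected > 0) k / expected else NA_real_
  )
}

#' Overlap enrichment between two identifier sets
#'
#' Convenience wrapper around [hypergeom_overlap()] for identifier vectors.
#' The universe must be supplied explicitly: the test's significance is
#' meaningless against an unstated universe. Identifiers outside the
#' universe raise an error.
#'
#' @param set_a,set_b Character vectors of identifiers.
#' @param universe Character vector of all detectable identifiers.
#' @return A one-row tibble as in [hypergeom_overlap()], plus the adjusted
#'   p-value column is left to the caller (adjust across families with
#'   [bh_adjust()]).
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  stray <- setdiff(c(set_a, set_b), universe)
  if (length(stray) > 0L) {
    abort(sprintf("%d identifier(s) not in the universe (e.g. '%s').",
                  length(stray), stray[1]))
  }
  hypergeom_overlap(length(universe), length(set_a), length(set_b),
                    length(intersect(set_a, set_b)))
}

#' Read an identifier set from a one-ID-per-line text file
#'
#' @param path File path; blank lines are dropped.
#' @return Character vector of unique identifiers.
#' @export
read_id_set <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  unique(ids[nzchar(ids)])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: monotone, capped at 1, order-preserving
#' under the original indexing.
#'
#' @param p_values Numeric vector in (0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}
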