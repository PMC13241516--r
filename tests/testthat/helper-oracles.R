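# Independent oracles used across tests. These deliberately re-derive
# results by brute force / enumeration, not via the package's own code paths.

# Brute-force grayscale opening residual (rolling-ball oracle): min filter
# then max filter over a disc neighbourhood, out-of-image pixels ignored.
bf_opening_residual <- function(x, radius) {
  k <- outer((-radius:radius)^2, (-radius:radius)^2, "+") <= radius^2
  sweep_filter <- function(m, f) {
    out <- m
    for (i in seq_len(nrow(m))) {
      for (j in seq_len(ncol(m))) {
        vals <- numeric(0)
        for (di in -radius:radius) {
          for (dj in -radius:radius) {
            if (k[di + radius + 1, dj + radius + 1]) {
              ii <- i + di; jj <- j + dj
              if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m)) {
                vals <- c(vals, m[ii, jj])
              }
            }
          }
        }
        out[i, j] <- f(vals)
      }
    }
    out
  }
  x - sweep_filter(sweep_filter(x, min), max)
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of N with K marked elements and count draws with overlap >= k.
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)  # elements 1..K are the marked set
  mean(overlaps >= k)
}

# Hand-applied Benjamini-Hochberg step-up: sort, adj(i) = min_{j>=i} p(j)*m/j,
# cap at 1, undo the sort.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(rev(cummin(rev(ps * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Rasterized filled disc mask (pixel centres within radius r of the centre).
disc_mask <- function(r, pad = 5L) {
  n <- 2L * ceiling(r) + 2L * pad + 1L
  c0 <- (n + 1) / 2
  ix <- matrix(rep(seq_len(n), each = n), n)
  iy <- matrix(rep(seq_len(n), times = n), n)
  (ix - c0)^2 + (iy - c0)^2 <= r^2
}

# Small rendered scene shared by segmentation tests.
make_test_scene <- function(n_droplets = 10, size = 600, seed = 42, ...) {
  cfg <- scene_config(image_height_px = size, image_width_px = size,
                      n_droplets = n_droplets, rng_seed = seed, ...)
  suppressMessages(suppressWarnings(simulate_scene(cfg)))
}
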