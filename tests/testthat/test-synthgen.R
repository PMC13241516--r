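test_that("droplet sampling respects counts, bounds, and non-overlap", {
  cfg <- scene_config(n_droplets = 0)
  expect_identical(nrow(sample_droplets(cfg)), 0L)

  cfg <- scene_config(image_height_px = 900, image_width_px = 900,
                      n_droplets = 60, rng_seed = 7)
  d <- sample_droplets(cfg)
  expect_identical(nrow(d), 60L)
  expect_identical(anyDuplicated(d$droplet_id), 0L)
  # fully inside the image
  px <- cfg$pixel_size_um
  expect_true(all(d$center_x_um - d$radius_um >= 0))
  expect_true(all(d$center_x_um + d$radius_um <= (cfg$image_width_px - 1) * px))
  expect_true(all(d$center_y_um + d$radius_um <= (cfg$image_height_px - 1) * px))
  # pairwise non-overlap
  dist <- as.matrix(stats::dist(cbind(d$center_x_um, d$center_y_um)))
  rsum <- outer(d$radius_um, d$radius_um, "+")
  diag(dist) <- Inf
  expect_true(all(dist >= rsum))
  # deterministic for fixed seed
  expect_identical(d, sample_droplets(cfg))
})

test_that("sampled diameters follow the log-normal size model", {
  cfg <- scene_config(image_height_px = 1500, image_width_px = 1500,
                      n_droplets = 500, rng_seed = 3)
  d <- sample_droplets(cfg)
  med <- median(2 * d$radius_um)
  expect_lt(abs(med - exp(cfg$diam_log_mu)) / exp(cfg$diam_log_mu), 0.05)
})

test_that("an overcrowded scene fails with the achieved count", {
  cfg <- scene_config(image_height_px = 120, image_width_px = 120,
                      n_droplets = 200, rng_seed = 1)
  expect_error(sample_droplets(cfg), "scene too crowded")
})

test_that("condensate injection respects probability, certainty, and containment", {
  cfg0 <- scene_config(n_droplets = 20, condensate_prob = 0, rng_seed = 5)
  d0 <- sample_droplets(cfg0)
  expect_identical(nrow(inject_condensates(d0, cfg0)), 0L)

  cfg1 <- scene_config(image_height_px = 900, image_width_px = 900,
                       n_droplets = 50, condensate_prob = 1, rng_seed = 5)
  d1 <- sample_droplets(cfg1)
  co <- suppressWarnings(inject_condensates(d1, cfg1))
  expect_setequal(unique(co$parent_droplet_id), d1$droplet_id)
  expect_identical(anyDuplicated(co$condensate_id), 0L)
  # every mask pixel inside the parent disc
  px <- cfg1$pixel_size_um
  inside <- mapply(function(m, pid) {
    dd <- d1[d1$droplet_id == pid, ]
    x <- (m[, "col"] - 1) * px
    y <- (m[, "row"] - 1) * px
    all((x - dd$center_x_um)^2 + (y - dd$center_y_um)^2 <= dd$radius_um^2)
  }, co$pixel_mask, co$parent_droplet_id)
  expect_true(all(inside))
  # masks are 8-connected
  conn <- vapply(co$pixel_mask, function(m) {
    rg <- apply(m, 2, range)
    M <- matrix(0L, rg[2, 1] - rg[1, 1] + 1, rg[2, 2] - rg[1, 2] + 1)
    M[cbind(m[, 1] - rg[1, 1] + 1, m[, 2] - rg[1, 2] + 1)] <- 1L
    max(ceodr:::label_components_8(M))
  }, integer(1))
  expect_true(all(conn == 1L))
})

test_that("rendering is deterministic and couples intensity to diameter", {
  sc <- make_test_scene(n_droplets = 0, size = 100, seed = 9)
  bg <- sc$channels$reporter$values
  expect_lt(abs(mean(bg) - 200), 25)  # pure noise around the camera offset

  sc1 <- make_test_scene(n_droplets = 15, size = 500, seed = 11)
  sc2 <- make_test_scene(n_droplets = 15, size = 500, seed = 11)
  expect_identical(sc1$channels$reporter$values, sc2$channels$reporter$values)
  expect_identical(sc1$channels$marker$values, sc2$channels$marker$values)

  # 200 droplets, positive slope, noise on -> strong intensity-diameter rank
  # correlation of per-droplet mean reporter intensity
  cfg <- scene_config(image_height_px = 1500, image_width_px = 1500,
                      n_droplets = 200, rng_seed = 13, condensate_prob = 0)
  sc <- suppressMessages(simulate_scene(cfg))
  px <- cfg$pixel_size_um
  mean_int <- vapply(seq_len(nrow(sc$droplets)), function(i) {
    d <- sc$droplets[i, ]
    jj <- pmax(1, floor((d$center_x_um - d$radius_um) / px)):
      pmin(1500, ceiling((d$center_x_um + d$radius_um) / px) + 1)
    ii <- pmax(1, floor((d$center_y_um - d$radius_um) / px)):
      pmin(1500, ceiling((d$center_y_um + d$radius_um) / px) + 1)
    sub <- sc$channels$reporter$values[ii, jj]
    xs <- (jj - 1) * px; ys <- (ii - 1) * px
    inside <- outer((ys - d$center_y_um)^2, (xs - d$center_x_um)^2, "+") <= d$radius_um^2
    mean(sub[inside])
  }, numeric(1))
  rho <- cor(mean_int, 2 * sc$droplets$radius_um, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("FRAP trace simulation matches the closed-form recovery", {
  tr <- simulate_frap_trace(rate_k_per_s = log(2), post_bleach_level = 20,
                            plateau = 90, dt_s = 1, duration_s = 10,
                            noise_sd = 0)
  post <- tr[tr$time_s >= 0, ]
  expect_equal(post$bleach[post$time_s == 0], 20)
  # half-life definition: at t = 1 s with k = ln 2 the signal is midway
  expect_equal(post$bleach[post$time_s == 1], (20 + 90) / 2)
  # long-time limit approaches the plateau
  tr2 <- simulate_frap_trace(0.1, dt_s = 0.5, duration_s = 180, noise_sd = 0)
  expect_lt(abs(tr2$bleach[nrow(tr2)] - 90), 1e-6 * 90)
  # noiseless traces satisfy I(t_half) = (I0 + P)/2 to within 1e-9
  for (k in c(0.05, 0.5, 2)) {
    t_half <- log(2) / k
    tr3 <- simulate_frap_trace(k, dt_s = t_half, duration_s = 10 * t_half,
                               noise_sd = 0)
    expect_lt(abs(tr3$bleach[tr3$time_s == t_half] - (20 + 90) / 2), 1e-9)
  }
  expect_error(simulate_frap_trace(0.1, noise_sd = -1), "noise_sd")
})

test_that("scene export round-trips images and ground-truth tables", {
  sc <- make_test_scene(n_droplets = 12, size = 400, seed = 21)
  dir <- withr::local_tempdir()
  paths <- export_scene(sc$channels, sc$droplets, sc$condensates, dir)
  back <- read_pixel_grid(paths[["reporter"]], sc$config$pixel_size_um)
  expect_identical(back$values, unname(sc$channels$reporter$values) + 0)
  dtab <- read.csv(paths[["droplets"]])
  expect_identical(nrow(dtab), 12L)
  expect_named(dtab, c("id", "cx_um", "cy_um", "radius_um", "fill_intensity",
                       "n_condensates"))
  expect_equal(dtab$radius_um, sc$droplets$radius_um)
  # empty condensate list -> header-only CSV
  paths2 <- export_scene(sc$channels, sc$droplets,
                         inject_condensates(sc$droplets,
                                            scene_config(condensate_prob = 0)),
                         withr::local_tempdir())
  ctab <- read.csv(paths2[["condensates"]])
  expect_identical(nrow(ctab), 0L)
  expect_named(ctab, c("id", "parent_id", "area_um2", "perimeter_um"))
})

test_that("scene configuration validates and round-trips through JSON", {
  expect_error(scene_config(condensate_prob = 1.2), "condensate_prob")
  expect_error(scene_config(diam_log_sigma = -1), "diam_log_sigma")
  expect_error(scene_config(pixel_size_um = 0), "pixel_size_um")
  cfg <- scene_config(n_droplets = 17, rng_seed = 99, diam_log_mu = 3.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene_config(cfg, path)
  expect_identical(read_scene_config(path), cfg)
})
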