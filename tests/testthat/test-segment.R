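test_that("rolling-ball subtraction equals the brute-force opening residual", {
  set.seed(101)
  for (rep in 1:4) {
    x <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    g <- pixel_grid(x + 0, pixel_size_um = 1, bit_depth = 8L)
    got <- subtract_background_rolling_ball(g, 3)$values
    want <- bf_opening_residual(x / 255, 3) * 255
    expect_equal(got, want, tolerance = 1e-9)
    expect_true(all(got >= 0))
    expect_true(all(got <= x + 1e-9))  # opening never exceeds the input
  }
})

test_that("rolling-ball removes flat backgrounds and is offset-invariant", {
  const <- pixel_grid(matrix(117, 40, 40), 1, 8L)
  expect_true(all(subtract_background_rolling_ball(const, 5)$values == 0))

  set.seed(7)
  f <- matrix(sample(0:100, 32 * 32, replace = TRUE), 32, 32)
  a <- subtract_background_rolling_ball(pixel_grid(f + 0, 1, 8L), 4)$values
  b <- subtract_background_rolling_ball(pixel_grid(f + 80, 1, 8L), 4)$values
  expect_equal(a, b, tolerance = 1e-9)

  # a narrow bright peak survives a much wider ball almost unchanged
  img <- matrix(20, 61, 61)
  img[30:32, 30:32] <- 220
  out <- subtract_background_rolling_ball(pixel_grid(img, 1, 8L), 25)$values
  expect_gt(max(out), 0.95 * 200)
  expect_error(subtract_background_rolling_ball(pixel_grid(img, 1, 8L), 40),
               "exceeds the image extent")
})

test_that("droplet segmentation recovers well-separated droplets exactly", {
  set.seed(1234)
  blank <- pixel_grid(matrix(pmax(rnorm(90000, 200, 50), 0), 300, 300), 0.65, 16L)
  expect_identical(n_labels(segment_droplets(blank)), 0L)

  sc <- make_test_scene(n_droplets = 10, size = 600, seed = 42)
  dm <- segment_droplets(sc$channels$reporter)
  expect_identical(n_labels(dm), 10L)
  mo <- measure_objects(dm)
  px <- sc$config$pixel_size_um
  for (i in seq_len(10)) {
    dmin <- min(sqrt((sc$droplets$center_x_um - mo$centroid_x_um[i])^2 +
                       (sc$droplets$center_y_um - mo$centroid_y_um[i])^2))
    expect_lt(dmin, 1 * px)  # centroid within one pixel of ground truth
  }
})

test_that("border-touching droplets are excluded when requested", {
  v <- matrix(100, 120, 120)
  ix <- matrix(rep(1:120, each = 120), 120)
  iy <- matrix(rep(1:120, times = 120), 120)
  v[(ix - 60)^2 + (iy - 60)^2 <= 15^2] <- 40000   # interior droplet
  v[(ix - 3)^2 + (iy - 60)^2 <= 15^2] <- 40000    # clipped by the edge
  g <- pixel_grid(v, 0.65, 16L)
  p_keep <- segmentation_params(droplet_threshold = 20000,
                                exclude_border = FALSE,
                                droplet_gaussian_sigma_px = 0,
                                droplet_min_area_um2 = 0)
  p_drop <- segmentation_params(droplet_threshold = 20000,
                                exclude_border = TRUE,
                                droplet_gaussian_sigma_px = 0,
                                droplet_min_area_um2 = 0)
  expect_identical(n_labels(segment_droplets(g, p_keep)), 2L)
  expect_identical(n_labels(segment_droplets(g, p_drop)), 1L)
})

test_that("condensate segmentation applies the 8-bit-equivalent threshold of 60", {
  # uniform value below threshold after background removal -> nothing
  v <- matrix(0, 80, 80)
  v[30:49, 30:49] <- 59 * 257   # 20 px square at 8-bit-equivalent 59
  g <- pixel_grid(v, 0.65, 16L)
  p <- segmentation_params(condensate_denoise_radius_px = 0,
                           rolling_ball_radius_px = 30,
                           condensate_min_area_px = 1)
  expect_identical(n_labels(segment_condensates(g, p)), 0L)
  v[30:49, 30:49] <- 200 * 257  # one bright blob on background 10
  g2 <- pixel_grid(v + 10, 0.65, 16L)
  expect_identical(n_labels(segment_condensates(g2, p)), 1L)
})

test_that("condensates are recovered from a rendered scene with ground truth", {
  sc <- make_test_scene(n_droplets = 40, size = 800, seed = 33)
  cm <- segment_condensates(sc$channels$marker)
  det <- cm$labels > 0
  hit <- vapply(sc$condensates$pixel_mask,
                function(m) mean(det[m]) >= 0.5, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("mother-child assignment follows centroid, overlap, and orphan rules", {
  px <- 1
  D <- matrix(0L, 20, 20)
  D[2:9, 2:9] <- 1L      # droplet 1
  D[12:19, 12:19] <- 2L  # droplet 2
  dm <- label_map(D, px)

  C <- matrix(0L, 20, 20)
  C[4:6, 4:6] <- 1L     # fully inside droplet 1
  C[14:16, 2:4] <- 2L   # overlaps no droplet -> orphan
  C[8:11, 5:7] <- 3L    # straddles droplet 1's edge, centroid pixel outside
  C[6:11, 8:9] <- 4L    # straddles the edge with centroid still inside
  cm <- label_map(C, px)
  pa <- assign_condensates(dm, cm)
  expect_identical(nrow(pa), 4L)
  expect_identical(pa$parent_label[pa$condensate_label == 1], 1L)
  expect_identical(pa$method[pa$condensate_label == 1], "centroid")
  expect_true(is.na(pa$parent_label[pa$condensate_label == 2]))
  expect_identical(pa$method[pa$condensate_label == 2], "orphan")
  # centroid row 9.5 rounds outside droplet 1 (rows 2:9); the largest pixel
  # overlap (rows 8:9) decides
  expect_identical(pa$parent_label[pa$condensate_label == 3], 1L)
  expect_identical(pa$method[pa$condensate_label == 3], "overlap")
  # centroid row 8.5 rounds to 8, inside droplet 1
  expect_identical(pa$parent_label[pa$condensate_label == 4], 1L)
  expect_identical(pa$method[pa$condensate_label == 4], "centroid")
  # each child assigned exactly once
  expect_identical(anyDuplicated(pa$condensate_label), 0L)
  expect_error(
    assign_condensates(dm, label_map(matrix(0L, 10, 10), px)),
    "dimensions differ"
  )
})

test_that("label maps are consecutive and scan-order stable", {
  m <- matrix(0L, 10, 10)
  m[8:9, 1:2] <- 1L   # later in scan order
  m[1:2, 5:6] <- 1L   # first object encountered row-wise
  m[5, 9] <- 1L
  L <- ceodr:::label_components_8(m)
  expect_identical(sort(unique(as.integer(L))), 0:3)
  expect_identical(L[1, 5], 1L)  # first in row-major scan
  expect_identical(L[5, 9], 2L)
  expect_identical(L[8, 1], 3L)
  # diagonal touching pixels belong to one 8-connected object
  d8 <- matrix(0L, 5, 5); d8[2, 2] <- 1L; d8[3, 3] <- 1L; d8[4, 2] <- 1L
  expect_identical(max(ceodr:::label_components_8(d8)), 1L)
})

test_that("channel loading guards against mismatched or colour input", {
  sc <- make_test_scene(n_droplets = 5, size = 200, seed = 2)
  dir <- withr::local_tempdir()
  paths <- export_scene(sc$channels, sc$droplets, sc$condensates, dir)
  ch <- load_channels(paths[["reporter"]], paths[["marker"]], 0.65)
  expect_identical(ch$reporter$values, unname(sc$channels$reporter$values) + 0)

  small <- file.path(dir, "small.tif")
  tiff::writeTIFF(matrix(0.5, 50, 50), small, bits.per.sample = 16)
  expect_error(load_channels(paths[["reporter"]], small, 0.65),
               "dimensions differ")
  rgb <- file.path(dir, "rgb.tif")
  tiff::writeTIFF(array(0.5, c(20, 20, 3)), rgb)
  expect_error(read_pixel_grid(rgb, 0.65), "channel")
  expect_error(read_pixel_grid(file.path(dir, "nope.tif"), 0.65), "not found")
})
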