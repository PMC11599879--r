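test_that("wrapping a straight band returns its seaward edge", {
  sc <- generate_scene(scene_config(nx = 60, ny = 80, band_width = 900,
                                    region_size_px = 60), seed = 1)
  cl <- wrap_coastline(sc$mask, sc$ocean, tolerance = 15)
  expect_true(all(abs(cl[, 2] - 600) < 1e-9))
  expect_equal(nrow(cl), 2L)  # simplified to one straight segment
})

test_that("all mangrove pixels lie landward of the wrapped coastline", {
  # two disjoint patches at different cross-shore positions
  m <- matrix(0L, 40, 60)
  m[10:15, 5:20] <- 1L
  m[20:28, 35:55] <- 1L
  o <- matrix(0L, 40, 60); o[1:5, ] <- 1L
  mg <- raster_grid(m); og <- raster_grid(o)
  cl <- wrap_coastline(mg, og, tolerance = 0)
  ctr <- grid_centers(mg, which(m == 1, arr.ind = TRUE))
  edge_y <- approx(cl[, 1], cl[, 2], xout = ctr[, 1], rule = 2)$y
  expect_true(all(ctr[, 2] >= edge_y - 1e-9))
})

test_that("simplification tolerance reduces vertex count monotonically", {
  cfg <- scene_config(nx = 200, ny = 120, band_width = 900,
                      coast = list(type = "sinusoidal", y0 = 900,
                                   amplitude = 300, wavelength = 2000),
                      region_size_px = 200)
  sc <- generate_scene(cfg, seed = 1)
  v0 <- nrow(wrap_coastline(sc$mask, sc$ocean, tolerance = 0))
  v1 <- nrow(wrap_coastline(sc$mask, sc$ocean, tolerance = 30))
  v2 <- nrow(wrap_coastline(sc$mask, sc$ocean, tolerance = 300))
  expect_true(v0 >= v1 && v1 >= v2)
})

test_that("a straight 10 km coastline at 1 km spacing yields 11 parallel landward transects", {
  coast <- cbind(c(0, 10000), c(0, 0))
  ocean <- raster_grid(rbind(matrix(1L, 2, 10), matrix(0L, 8, 10)),
                       origin = c(0, -2000), pixel_size = 1000)
  tr <- build_transects(coast, spacing = 1000, length = 5000,
                        ocean_mask = ocean)
  expect_equal(nrow(tr), 11L)
  expect_equal(tr$dx, rep(0, 11))
  expect_equal(tr$dy, rep(1, 11))
  expect_equal(tr$x, seq(0, 10000, by = 1000))
})

test_that("reversing the ocean side flips every transect direction exactly", {
  coast <- cbind(c(0, 10000), c(0, 0))
  below <- raster_grid(rbind(matrix(1L, 2, 12), matrix(0L, 8, 12)),
                       origin = c(-1000, -2000), pixel_size = 1000)
  above <- raster_grid(rbind(matrix(0L, 8, 12), matrix(1L, 2, 12)),
                       origin = c(-1000, -8000), pixel_size = 1000)
  t1 <- build_transects(coast, 1000, 5000, ocean_mask = below)
  t2 <- build_transects(coast, 1000, 5000, ocean_mask = above)
  expect_equal(t1$dx, -t2$dx)
  expect_equal(t1$dy, -t2$dy)
})

test_that("transects are perpendicular to a sinusoidal coast within 1e-6 rad", {
  amp <- 50; wl <- 2000
  xs <- seq(0, 2000, by = 0.05)
  coast <- cbind(xs, amp * sin(2 * pi * xs / wl))
  tr <- build_transects(coast, spacing = 200, length = 1000,
                        ocean_mask = NULL, tangent_window = 1)
  f1 <- function(x) amp * 2 * pi / wl * cos(2 * pi * x / wl)
  for (i in seq_len(nrow(tr))) {
    tan_a <- c(1, f1(tr$x[i])); tan_a <- tan_a / sqrt(sum(tan_a^2))
    # angle between transect direction and the analytic tangent minus 90 deg
    cross <- abs(tr$dx[i] * tan_a[1] + tr$dy[i] * tan_a[2])
    expect_lt(asin(min(cross, 1)), 1e-6)
  }
})

test_that("segmented mangrove lines sum: 10 pixels, a gap, then 5 more give N = 15", {
  m <- matrix(0L, 30, 3)
  m[3:12, 2] <- 1L   # 10 consecutive pixels
  m[15:19, 2] <- 1L  # gap of 2, then 5 more
  sc <- manual_scene(m, height = 7)
  s <- sample_transect(sc, list(index = 1L, x = 45, y = 0, dx = 0, dy = 1,
                                length = 900))
  expect_equal(s$n, 15L)
  expect_equal(30 * s$n, 450)  # implied width C x N
  expect_equal(s$mean_height, 7)
  expect_true(s$contains)
})

test_that("a transect over open water or outside the raster samples nothing", {
  m <- matrix(0L, 30, 3); m[5:10, 2] <- 1L
  sc <- manual_scene(m)
  over_water <- sample_transect(sc, list(index = 1L, x = 15, y = 0,
                                         dx = 0, dy = -1, length = 900))
  expect_equal(over_water$n, 0L)
  expect_false(over_water$contains)
  expect_true(is.na(over_water$mean_height))
  outside <- sample_transect(sc, list(index = 2L, x = -5000, y = 0,
                                      dx = 0, dy = 1, length = 900))
  expect_equal(outside$n, 0L)
})

test_that("region aggregation averages widths and per-transect means", {
  samples <- data.frame(index = 1:3,
                        n = c(10L, 30L, 0L),
                        mean_height = c(4, 8, NA),
                        mean_ndvi = c(0.6, 0.8, NA),
                        contains = c(TRUE, TRUE, FALSE))
  rec <- aggregate_region(samples, region_id = 1, epoch = 2019,
                          pixel_size = 30)
  expect_equal(rec$amw_m, 600)   # mean of 300 and 900
  expect_equal(rec$ach_m, 6)     # mean of per-transect means
  expect_equal(rec$ndvi, 0.7)
  expect_equal(rec$m, 3L)
  expect_equal(rec$n, 2L)
  # empty transects dilute AMW only when explicitly included
  rec2 <- aggregate_region(samples, 1, 2019, 30, include_empty = TRUE)
  expect_equal(rec2$amw_m, 400)
  expect_equal(rec2$ach_m, 6)
  # all-empty region yields no record
  empty <- samples[3, ]
  expect_null(aggregate_region(empty, 1, 2019, 30))
})

test_that("height aggregation is a mean of transect means, not a pooled pixel mean", {
  m <- matrix(0L, 30, 3)
  m[3:4, 1] <- 1L     # short transect: 2 pixels
  m[3:6, 3] <- 1L     # long transect: 4 pixels
  h <- matrix(0, 30, 3)
  h[3:4, 1] <- c(2, 4)
  h[3:6, 3] <- 8
  sc <- manual_scene(m, height = h)
  tr <- data.frame(index = 1:2, x = c(15, 75), y = 0, dx = 0, dy = 1,
                   length = 900)
  recs <- aggregate_region(sample_transects(sc, tr), 1, 2019, 30)
  pooled <- mean(c(2, 4, 8, 8, 8, 8))
  expect_equal(recs$ach_m, mean(c(3, 8)))   # 5.5, the double mean
  expect_false(isTRUE(all.equal(recs$ach_m, pooled)))
})

test_that("regions recover the configured ground truth on a noiseless scene", {
  cfg <- demo_scene_config()
  sc <- generate_scene(cfg, seed = 1)
  recs <- extract_regions(sc, spacing = 300)
  recs <- recs[order(recs$region_id), ]
  expect_equal(nrow(recs), nrow(sc$truth))
  expect_true(all(abs(recs$amw_m - sc$truth$true_width_m) <= 30))
  expect_equal(recs$ach_m, sc$truth$true_height_m, tolerance = 1e-9)
  expect_equal(recs$ndvi, sc$truth$true_ndvi, tolerance = 1e-7)
})

test_that("only tiles containing mangrove produce records", {
  cfg <- demo_scene_config(
    widths = c(900, 0, 900, 0, 900, 0, 0, 0),
    heights = 8, ndvi = 0.7, region_size_px = 25, nx = 200)
  sc <- generate_scene(cfg, seed = 1)
  recs <- extract_regions(sc, spacing = 150)
  expect_equal(sort(recs$region_id), c(1L, 3L, 5L))
})

test_that("doubling the transect spacing barely moves AMW on a homogeneous band", {
  cfg <- demo_scene_config(widths = 1200, heights = 8, ndvi = 0.7,
                           region_size_px = 200)
  sc <- generate_scene(cfg, seed = 1)
  a <- extract_regions(sc, spacing = 300)$amw_m
  b <- extract_regions(sc, spacing = 600)$amw_m
  expect_lt(abs(a - b), 30)
})

test_that("degenerate inputs raise the documented errors", {
  sc <- generate_scene(demo_scene_config(), seed = 1)
  empty <- raster_grid(matrix(0L, 10, 10))
  expect_error(wrap_coastline(empty, empty), "no mangrove")
  expect_error(build_transects(cbind(c(0, 0), c(0, 0)), 1000, 1000),
               "degenerate")
  expect_error(extract_regions(sc, regions = sc$regions[0, ]), "empty region")
})
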