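# Fixtures are built in code; nothing is read from disk.

# hand-assembled scene from raw matrices (row 1 = lowest y)
manual_scene <- function(mask, height = 0, ndvi = 0.7, pixel_size = 30,
                         ocean = NULL, epoch = 2019) {
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (length(height) == 1) height <- matrix(height, nrow(mask), ncol(mask))
  height[mask == 0] <- 0
  if (length(ndvi) == 1) ndvi <- matrix(ndvi, nrow(mask), ncol(mask))
  red <- matrix(0.1, nrow(mask), ncol(mask))
  nir <- red * (1 + ndvi) / (1 - ndvi)
  if (is.null(ocean)) {
    ocean <- matrix(0L, nrow(mask), ncol(mask))
    ocean[1, ] <- 1L   # thin ocean strip at the bottom
  }
  structure(list(
    epoch = epoch,
    mask = raster_grid(mask, pixel_size = pixel_size),
    height = raster_grid(height, pixel_size = pixel_size),
    red = raster_grid(red, pixel_size = pixel_size),
    nir = raster_grid(nir, pixel_size = pixel_size),
    ocean = raster_grid(ocean, pixel_size = pixel_size),
    coastline = cbind(c(0, ncol(mask) * pixel_size), c(0, 0)),
    regions = data.frame(region_id = 1L, xmin = 0,
                         xmax = ncol(mask) * pixel_size, ymin = 0,
                         ymax = nrow(mask) * pixel_size),
    truth = NULL, pixel_size = pixel_size, config = NULL
  ), class = "coast_scene")
}

# a small multi-region noiseless scene used by several suites
demo_scene_config <- function(widths = c(600, 900, 1200, 1500),
                              heights = c(4, 6, 8, 12),
                              ndvi = c(0.55, 0.65, 0.7, 0.8),
                              region_size_px = 50, nx = 200, ny = 120,
                              fragmentation = 0, ...) {
  scene_config(nx = nx, ny = ny, pixel_size = 30,
               coast = list(type = "straight", y0 = 600),
               region_size_px = region_size_px,
               band_width = widths, heights = heights, ndvi = ndvi,
               fragmentation = fragmentation, ...)
}

# well-separated direction archetypes in the positive octant (for clustering)
archetype_directions <- function() {
  sph <- rbind(
    c(10, 15), c(35, 15), c(60, 15), c(80, 15),
    c(15, 45), c(50, 45), c(85, 45), c(45, 80))
  t(apply(sph, 1, function(ae) {
    az <- ae[1] * pi / 180; el <- ae[2] * pi / 180
    c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  }))
}

# noisy feature matrix with planted archetype labels
archetype_features <- function(per = 6, noise_sd = 0.01, seed = 7) {
  set.seed(seed)
  A <- archetype_directions()
  lab <- rep(seq_len(nrow(A)), each = per)
  X <- A[lab, ] + matrix(rnorm(length(lab) * 3, 0, noise_sd),
                         ncol = 3)
  X <- pmax(X, 0)
  colnames(X) <- c("amw", "ach", "ndvi")
  rownames(X) <- sprintf("r%03d", seq_along(lab))
  attr(X, "region_id") <- seq_along(lab)
  attr(X, "epoch") <- rep(2019, length(lab))
  list(X = X, labels = lab)
}
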