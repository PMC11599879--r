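#' Configuration for a synthetic coastal scene
#'
#' Describes a shore-parallel mangrove band on a planar raster: coastline
#' shape, per-region cross-shore band width, canopy height field, target NDVI
#' realized through a red/NIR reflectance pair, and optional fragmentation
#' (random gap pixels inside the band). Regions are rectangular tiles along
#' the shore, the desk-scale analogue of coarse analysis grid cells. The
#' ocean lies on the decreasing-y side of the coastline by convention and the
#' scene carries an explicit ocean mask.
#'
#' @param nx,ny raster size in pixels (x = alongshore, y = cross-shore).
#' @param pixel_size pixel edge in metres (default 30, the sampling distance
#'   `C` used throughout).
#' @param coast coastline shape: `list(type = "straight", y0 = <m>)` or
#'   `list(type = "sinusoidal", y0, amplitude, wavelength)` (metres).
#' @param region_size_px tile width along x in pixels; the scene is split
#'   into `ceiling(nx / region_size_px)` regions.
#' @param band_width cross-shore mangrove width: a scalar (metres), a
#'   per-region vector, or `list(type = "lognormal", median, sigma)` drawn
#'   once per region.
#' @param heights canopy height over the band: scalar, per-region vector, or
#'   `list(type = "gradient", from, to)` linear alongshore (metres).
#' @param ndvi target NDVI over the band: scalar or per-region vector,
#'   strictly inside (-1, 1).
#' @param red red-band reflectance used for mangrove pixels; lowered per
#'   region where needed so the solved NIR stays below 1.
#' @param fragmentation probability in `[0, 1]` that a band pixel is a gap
#'   (bare ground) rather than mangrove.
#' @param height_noise_sd,refl_noise_sd optional Gaussian noise (metres /
#'   reflectance units) added to the height and reflectance fields; defaults
#'   0 (noiseless ground truth).
#' @param epoch epoch label (year).
#' @return object of class `scene_config`.
#' @export
scene_config <- function(nx = 400, ny = 120, pixel_size = 30,
                         coast = list(type = "straight", y0 = 600),
                         region_size_px = 100,
                         band_width = 900,
                         heights = 8,
                         ndvi = 0.7,
                         red = 0.1,
                         fragmentation = 0,
                         height_noise_sd = 0,
                         refl_noise_sd = 0,
                         epoch = 2019) {
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny),
              pixel_size = pixel_size, coast = coast,
              region_size_px = as.integer(region_size_px),
              band_width = band_width, heights = heights, ndvi = ndvi,
              red = red, fragmentation = fragmentation,
              height_noise_sd = height_noise_sd,
              refl_noise_sd = refl_noise_sd, epoch = epoch)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (cfg$pixel_size <= 0) stop("configuration error: pixel size must be > 0")
  if (cfg$nx < 1 || cfg$ny < 1) stop("configuration error: empty raster")
  if (!cfg$coast$type %in% c("straight", "sinusoidal"))
    stop("configuration error: unknown coastline type")
  w <- cfg$band_width
  if (is.numeric(w) && any(w < 0))
    stop("configuration error: band widths must be >= 0")
  h <- cfg$heights
  if (is.numeric(h) && any(h < 0))
    stop("configuration error: heights must be >= 0")
  if (is.list(h) && identical(h$type, "gradient") &&
      (h$from < 0 || h$to < 0))
    stop("configuration error: heights must be >= 0")
  v <- cfg$ndvi
  if (any(v <= -1 | v >= 1))
    stop("configuration error: NDVI targets must lie in (-1, 1)")
  if (cfg$fragmentation < 0 || cfg$fragmentation > 1)
    stop("configuration error: fragmentation must be in [0, 1]")
  # the band must fit the raster (checked for deterministic widths)
  amp <- if (cfg$coast$type == "sinusoidal") cfg$coast$amplitude else 0
  if (is.numeric(w)) {
    need <- cfg$coast$y0 + amp + max(w)
    if (need > cfg$ny * cfg$pixel_size)
      stop("configuration error: raster too small to contain the band")
  }
  if (cfg$coast$y0 - amp < 0)
    stop("configuration error: coastline leaves the raster")
  invisible(cfg)
}

# region tiles along x
scene_regions <- function(cfg) {
  n <- ceiling(cfg$nx / cfg$region_size_px)
  xs <- (seq_len(n) - 1L) * cfg$region_size_px * cfg$pixel_size
  xe <- pmin(seq_len(n) * cfg$region_size_px, cfg$nx) * cfg$pixel_size
  data.frame(region_id = seq_len(n), xmin = xs, xmax = xe,
             ymin = 0, ymax = cfg$ny * cfg$pixel_size)
}

coast_y_fun <- function(coast) {
  if (coast$type == "straight") {
    function(x) rep(coast$y0, length(x))
  } else {
    function(x) coast$y0 + coast$amplitude * sin(2 * pi * x / coast$wavelength)
  }
}

resolve_region_param <- function(p, n_regions, what, cfg) {
  if (is.list(p)) {
    if (identical(p$type, "lognormal")) {
      return(stats::rlnorm(n_regions, meanlog = log(p$median), sdlog = p$sigma))
    }
    if (identical(p$type, "gradient")) return(NULL) # handled per pixel
    stop("configuration error: unknown ", what, " specification")
  }
  rep_len(p, n_regions)
}

#' Generate a synthetic coastal scene
#'
#' Builds co-registered rasters (mangrove mask, canopy height, red and NIR
#' reflectance, ocean mask), the coastline polyline, region tiles and a
#' ground-truth table. The recorded true width per region is the configured
#' width discretized to whole pixels (before fragmentation); true height and
#' NDVI are means over the realized mangrove pixels of the region. All
#' randomness is governed by `seed`, so identical `(config, seed)` give
#' bit-identical scenes.
#'
#' @param config a [scene_config()].
#' @param seed integer random seed.
#' @return object of class `coast_scene` with fields `epoch`, `mask`,
#'   `height`, `red`, `nir`, `ocean`, `coastline`, `regions`, `truth`,
#'   `pixel_size`, `config`.
#' @export
generate_scene <- function(config, seed = 1L) {
  validate_scene_config(config)
  set.seed(seed)
  C <- config$pixel_size
  nx <- config$nx; ny <- config$ny
  regions <- scene_regions(config)
  nr <- nrow(regions)

  widths <- resolve_region_param(config$band_width, nr, "band width", config)
  if (is.numeric(widths) &&
      any(config$coast$y0 + widths > ny * C))
    stop("configuration error: raster too small to contain the band")
  band_px <- pmax(0L, as.integer(round(widths / C)))

  xc <- (seq_len(nx) - 0.5) * C        # pixel-centre x
  yc <- (seq_len(ny) - 0.5) * C        # pixel-centre y
  coast_y <- coast_y_fun(config$coast)(xc)
  region_of_col <- pmin(((seq_len(nx) - 1L) %/% config$region_size_px) + 1L, nr)

  Y <- matrix(yc, nrow = ny, ncol = nx)
  CY <- matrix(coast_y, nrow = ny, ncol = nx, byrow = TRUE)
  Wm <- matrix(widths[region_of_col] , nrow = ny, ncol = nx, byrow = TRUE)
  BPX <- matrix(band_px[region_of_col], nrow = ny, ncol = nx, byrow = TRUE)

  ocean <- Y < CY
  band <- !ocean & (Y < CY + BPX * C)

  # gap pixels: always drawn over the band so the draw sequence (and hence
  # every later draw) is identical across fragmentation rates
  u <- matrix(NA_real_, ny, nx)
  u[band] <- stats::runif(sum(band))
  mask <- band & !(u < config$fragmentation)
  mask[is.na(mask)] <- FALSE

  # canopy height
  if (is.list(config$heights) && identical(config$heights$type, "gradient")) {
    hx <- config$heights$from +
      (config$heights$to - config$heights$from) * xc / (nx * C)
    H <- matrix(hx, nrow = ny, ncol = nx, byrow = TRUE)
  } else {
    hreg <- rep_len(config$heights, nr)
    H <- matrix(hreg[region_of_col], nrow = ny, ncol = nx, byrow = TRUE)
  }
  if (config$height_noise_sd > 0)
    H <- H + matrix(stats::rnorm(ny * nx, 0, config$height_noise_sd), ny, nx)
  H <- pmax(H, 0)
  height <- matrix(0, ny, nx)
  height[mask] <- H[mask]

  # reflectance pair realizing the target NDVI on mangrove pixels
  vreg <- rep_len(config$ndvi, nr)
  red_reg <- pmin(config$red, 0.9 * (1 - vreg) / (1 + vreg))
  nir_reg <- red_reg * (1 + vreg) / (1 - vreg)
  red <- matrix(0.20, ny, nx)            # bare land background
  nir <- matrix(0.25, ny, nx)
  red[ocean] <- 0.05; nir[ocean] <- 0.02 # water: slightly negative NDVI
  RR <- matrix(red_reg[region_of_col], ny, nx, byrow = TRUE)
  NN <- matrix(nir_reg[region_of_col], ny, nx, byrow = TRUE)
  red[mask] <- RR[mask]; nir[mask] <- NN[mask]
  if (config$refl_noise_sd > 0) {
    red <- red + matrix(stats::rnorm(ny * nx, 0, config$refl_noise_sd), ny, nx)
    nir <- nir + matrix(stats::rnorm(ny * nx, 0, config$refl_noise_sd), ny, nx)
  }
  red <- pmin(pmax(red, 0), 1); nir <- pmin(pmax(nir, 0), 1)

  # coastline polyline (smooth curve sampled at half-pixel steps)
  if (config$coast$type == "straight") {
    coastline <- cbind(c(0, nx * C), c(config$coast$y0, config$coast$y0))
  } else {
    xs <- seq(0, nx * C, by = C / 2)
    coastline <- cbind(xs, coast_y_fun(config$coast)(xs))
  }

  # ground truth per region
  truth <- regions[, "region_id", drop = FALSE]
  truth$true_width_m <- band_px * C
  truth$true_height_m <- NA_real_
  truth$true_ndvi <- NA_real_
  ndvi_px <- (nir - red) / (nir + red)
  for (k in seq_len(nr)) {
    cols <- which(region_of_col == k)
    mk <- mask[, cols, drop = FALSE]
    if (any(mk)) {
      truth$true_height_m[k] <- mean(height[, cols, drop = FALSE][mk])
      truth$true_ndvi[k] <- mean(ndvi_px[, cols, drop = FALSE][mk])
    }
  }

  structure(list(
    epoch = config$epoch,
    mask = raster_grid(mask, pixel_size = C),
    height = raster_grid(height, pixel_size = C),
    red = raster_grid(red, pixel_size = C),
    nir = raster_grid(nir, pixel_size = C),
    ocean = raster_grid(ocean, pixel_size = C),
    coastline = coastline,
    regions = regions,
    truth = truth,
    pixel_size = C,
    config = config
  ), class = "coast_scene")
}

#' @export
print.coast_scene <- function(x, ...) {
  cat(sprintf(
    "coast_scene: epoch %s, %d x %d px (%g m), %d regions, %d mangrove px\n",
    x$epoch, dim(x$mask$values)[2], dim(x$mask$values)[1], x$pixel_size,
    nrow(x$regions), sum(x$mask$values == 1)))
  invisible(x)
}

#' Per-pixel NDVI raster for a scene
#'
#' `(NIR - red) / (NIR + red)`; pixels where the denominator is not positive
#' are set to NA (treated as nodata).
#'
#' @param scene a `coast_scene`.
#' @return a [raster_grid] of NDVI values.
#' @export
ndvi_grid <- function(scene) {
  num <- scene$nir$values - scene$red$values
  den <- scene$nir$values + scene$red$values
  v <- ifelse(den > 0, num / den, NA_real_)
  raster_grid(v, origin = scene$mask$origin, pixel_size = scene$pixel_size)
}

#' Epoch-to-epoch change specification
#'
#' Multiplicative per-region factors applied to the configured width, height
#' and NDVI when generating the second epoch of a scene pair, plus optional
#' dieback patches where the mangrove mask is randomly thinned.
#'
#' @param width,height,ndvi positive factors, scalar or per-region.
#' @param dieback optional list of patches, each
#'   `list(xmin, xmax, ymin, ymax, prob)` in metres with thinning probability
#'   `prob` in `[0, 1]`.
#' @return object of class `change_spec`.
#' @export
change_spec <- function(width = 1, height = 1, ndvi = 1, dieback = NULL) {
  if (any(c(width, height, ndvi) <= 0))
    stop("configuration error: change factors must be > 0")
  for (p in dieback) {
    if (p$prob < 0 || p$prob > 1)
      stop("configuration error: dieback probability must be in [0, 1]")
  }
  structure(list(width = width, height = height, ndvi = ndvi,
                 dieback = dieback), class = "change_spec")
}

#' Generate a two-epoch scene pair with known change
#'
#' Epoch A is generated from `config`; epoch B from the same configuration
#' with widths, heights and NDVI targets multiplied by the change factors
#' (NDVI capped just below 1), using the same seed so that where the width
#' factor is 1 the mask is identical outside dieback patches. Dieback
#' thinning is applied to epoch B afterwards.
#'
#' @param config a [scene_config()].
#' @param change a [change_spec()].
#' @param seed integer seed.
#' @param epochs length-2 vector of epoch labels.
#' @return list of two `coast_scene` objects (epoch A, epoch B).
#' @export
generate_scene_pair <- function(config, change, seed = 1L,
                                epochs = c(2007, 2019)) {
  stopifnot(inherits(change, "change_spec"))
  nr <- nrow(scene_regions(config))
  cfg_a <- config
  cfg_a$epoch <- epochs[1]
  a <- generate_scene(cfg_a, seed)

  cfg_b <- config
  cfg_b$epoch <- epochs[2]
  if (is.list(config$band_width)) {
    # scale epoch A's realized widths so the pair shares one draw
    cfg_b$band_width <- a$truth$true_width_m * rep_len(change$width, nr)
  } else {
    cfg_b$band_width <- rep_len(config$band_width, nr) *
      rep_len(change$width, nr)
  }
  if (is.list(config$heights) && identical(config$heights$type, "gradient")) {
    hf <- rep_len(change$height, nr)
    if (length(unique(hf)) > 1L)
      stop("per-region height factors need per-region heights, not a gradient")
    cfg_b$heights <- list(type = "gradient",
                          from = config$heights$from * hf[1],
                          to = config$heights$to * hf[1])
  } else {
    cfg_b$heights <- rep_len(config$heights, nr) * rep_len(change$height, nr)
  }
  cfg_b$ndvi <- pmin(rep_len(config$ndvi, nr) * rep_len(change$ndvi, nr),
                     0.99)
  b <- generate_scene(cfg_b, seed)

  if (!is.null(change$dieback)) {
    for (p in change$dieback) {
      ctr <- grid_centers(b$mask,
                          which(b$mask$values == 1, arr.ind = TRUE))
      idx <- which(b$mask$values == 1, arr.ind = TRUE)
      inpatch <- ctr[, 1] >= p$xmin & ctr[, 1] < p$xmax &
        ctr[, 2] >= p$ymin & ctr[, 2] < p$ymax
      kill <- inpatch & stats::runif(nrow(idx)) < p$prob
      if (any(kill)) {
        ki <- idx[kill, , drop = FALSE]
        b$mask$values[ki] <- 0L
        b$height$values[ki] <- 0
        b$red$values[ki] <- 0.20
        b$nir$values[ki] <- 0.25
      }
    }
    # refresh realized truth after thinning
    b <- refresh_truth(b)
  }
  list(a, b)
}

refresh_truth <- function(scene) {
  ndvi_px <- ndvi_grid(scene)$values
  rc <- scene$regions
  region_of_col <- pmin(((seq_len(ncol(scene$mask$values)) - 1L) %/%
                           scene$config$region_size_px) + 1L, nrow(rc))
  for (k in seq_len(nrow(rc))) {
    cols <- which(region_of_col == k)
    mk <- scene$mask$values[, cols, drop = FALSE] == 1
    scene$truth$true_height_m[k] <-
      if (any(mk)) mean(scene$height$values[, cols, drop = FALSE][mk]) else NA
    scene$truth$true_ndvi[k] <-
      if (any(mk)) mean(ndvi_px[, cols, drop = FALSE][mk]) else NA
  }
  scene
}

#' Generate synthetic storm tracks crossing the coast
#'
#' Tracks run from offshore (low y) to inland (high y) across the scene at a
#' random alongshore position and heading, so every track intersects the
#' coastline; maximum sustained winds are drawn uniformly in `wind_range`.
#'
#' @param n number of storms (>= 0).
#' @param scene a `coast_scene` supplying the domain extent and coastline.
#' @param wind_range length-2 vector, knots.
#' @param seed integer seed.
#' @return list of `storm_track` objects
#'   (`track` polyline, `wind_kn`, `storm_id`, `time`).
#' @export
generate_storms <- function(n, scene, wind_range = c(40, 130), seed = 1L) {
  stopifnot(n >= 0)
  ext <- grid_extent(scene$mask)
  if (ext["xmax"] <= ext["xmin"] || ext["ymax"] <= ext["ymin"])
    stop("configuration error: empty domain")
  set.seed(seed)
  out <- vector("list", n)
  if (n == 0) return(out)
  L <- polyline_length(scene$coastline)
  for (i in seq_len(n)) {
    s <- stats::runif(1, 0.1, 0.9) * L
    pc <- point_along(scene$coastline, s)   # crossing point on the coast
    theta <- stats::runif(1, -pi / 6, pi / 6)
    dir <- c(sin(theta), cos(theta))        # roughly shore-normal, landward
    span <- (ext["ymax"] - ext["ymin"]) + 4000
    p0 <- c(pc) - dir * span / 2
    p2 <- c(pc) + dir * span / 2
    bend <- c(-dir[2], dir[1]) * stats::runif(1, -1000, 1000)
    track <- rbind(p0, c(pc) + bend * 0, (p0 + p2) / 2 + bend, p2)
    out[[i]] <- structure(
      list(track = track, wind_kn = stats::runif(1, wind_range[1],
                                                 wind_range[2]),
           storm_id = sprintf("storm-%03d", i),
           time = sprintf("event-%03d", i)),
      class = "storm_track")
  }
  out
}

#' Apply storm damage to a scene's NDVI
#'
#' Produces the "after" snapshot of a storm-validation experiment: inside the
#' supplied impact zones, pixel NDVI is lowered by an amount that decreases
#' with the region's protection index (damage
#' `= severity * (1 - MCPI / S) + noise`), encoding the hypothesis that
#' better-protected mangrove areas suffer less greenness loss. NIR is
#' re-solved from the damaged NDVI so the reflectance pair stays consistent.
#'
#' @param scene a `coast_scene` (the "before" snapshot).
#' @param zones impact zones from [impact_zones()].
#' @param records enriched region records (with `mcpi`), see
#'   [enrich_records()].
#' @param severity maximum NDVI drop at MCPI = 0.
#' @param noise_sd Gaussian noise on the per-zone damage.
#' @param scale index value at which damage vanishes; defaults to the
#'   largest MCPI among the records, so damage spans `[0, severity]` over
#'   the observed protection range.
#' @param seed integer seed.
#' @return a damaged copy of `scene`.
#' @export
damage_scene <- function(scene, zones, records, severity = 0.3,
                         noise_sd = 0, scale = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(scale)) scale <- max(records$mcpi, na.rm = TRUE)
  out <- scene
  # worst single-event damage per pixel: overlapping zones do not compound
  dmg_px <- matrix(0, nrow(scene$mask$values), ncol(scene$mask$values))
  for (z in zones) {
    for (rid in z$region_ids) {
      mcpi <- records$mcpi[match(rid, records$region_id)]
      if (length(mcpi) == 0 || is.na(mcpi)) next
      dmg <- severity * (1 - mcpi / scale) + stats::rnorm(1, 0, noise_sd)
      dmg <- max(dmg, 0)
      px <- z$pixels[z$pixel_region == rid, , drop = FALSE]
      if (nrow(px) == 0) next
      dmg_px[px] <- pmax(dmg_px[px], dmg)
    }
  }
  hit <- which(dmg_px > 0, arr.ind = TRUE)
  if (nrow(hit)) {
    red <- out$red$values[hit]
    nir <- out$nir$values[hit]
    v <- (nir - red) / (nir + red)
    v2 <- pmax(pmin(v - dmg_px[hit], 0.99), -0.99)
    out$nir$values[hit] <- red * (1 + v2) / (1 - v2)
  }
  out
}
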