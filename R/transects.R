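#' Outer-wrap coastline from a mangrove mask
#'
#' Traces the seaward edge of the mangrove band — for each raster column the
#' boundary of the most seaward mangrove pixel, seaward as indicated by the
#' ocean mask — and simplifies the resulting polyline with a Douglas-Peucker
#' tolerance. The result is the working coastline from which transects are
#' cast: every mangrove pixel lies on its landward side.
#'
#' @param mangrove_mask,ocean_mask co-registered boolean [raster_grid]s.
#' @param tolerance simplification tolerance in metres (0 keeps every
#'   vertex).
#' @return polyline vertex matrix (x, y).
#' @export
wrap_coastline <- function(mangrove_mask, ocean_mask, tolerance = 0) {
  stopifnot_registered(mangrove_mask, ocean_mask)
  m <- mangrove_mask$values == 1
  if (!any(m)) stop("empty domain: no mangrove pixels")
  C <- mangrove_mask$pixel_size
  org <- mangrove_mask$origin
  ocean_low <- ocean_side_low(ocean_mask)
  cols <- which(colSums(m) > 0)
  edge_y <- vapply(cols, function(j) {
    rows <- which(m[, j])
    if (ocean_low) org[2] + (min(rows) - 1L) * C    # seaward face of pixel
    else org[2] + max(rows) * C
  }, numeric(1))
  x <- org[1] + (cols - 0.5) * C
  p <- cbind(x, edge_y)
  if (nrow(p) == 1L) p <- rbind(p, p + c(C, 0))
  simplify_polyline(p, tolerance)
}

# TRUE if the ocean occupies the low-y side of the grid
ocean_side_low <- function(ocean_mask) {
  o <- ocean_mask$values == 1
  if (!any(o) || all(o)) return(TRUE)
  ny <- nrow(o)
  yo <- mean(row(o)[o]); yl <- mean(row(o)[!o])
  yo < yl
}

#' Cast equally spaced shore-perpendicular transects
#'
#' Anchors are placed at arc-length positions `0, spacing, 2*spacing, ...`
#' along the working coastline (`floor(L / spacing) + 1` transects); each
#' direction is the local coastline normal oriented landward, i.e. away from
#' the ocean mask.
#'
#' @param coastline polyline vertex matrix.
#' @param spacing anchor spacing in metres (default 1000).
#' @param length transect length in metres (default 30000; transects are
#'   clipped at the raster edge during sampling).
#' @param ocean_mask boolean [raster_grid] used to orient the normals; if
#'   NULL the ocean is assumed on the decreasing-y side.
#' @param tangent_window chord half-width for tangent estimation (metres);
#'   defaults to the mean segment length of `coastline`.
#' @return data.frame with one row per transect: `index`, anchor `x`, `y`,
#'   unit landward direction `dx`, `dy`, and `length`.
#' @export
build_transects <- function(coastline, spacing = 1000, length = 30000,
                            ocean_mask = NULL, tangent_window = NULL) {
  coastline <- as_polyline(coastline)
  stopifnot(spacing > 0, length > 0)
  L <- polyline_length(coastline)
  if (L <= 0) stop("geometry error: degenerate (zero-length) coastline")
  s <- seq(0, L, by = spacing)
  anchors <- point_along(coastline, s)
  tg <- polyline_tangent(coastline, s, window = tangent_window)
  normal <- cbind(-tg[, 2], tg[, 1])
  flip <- vapply(seq_len(nrow(anchors)), function(i) {
    landward_flip(anchors[i, ], normal[i, ], ocean_mask)
  }, logical(1))
  normal[flip, ] <- -normal[flip, , drop = FALSE]
  data.frame(index = seq_along(s), x = anchors[, 1], y = anchors[, 2],
             dx = normal[, 1], dy = normal[, 2], length = length)
}

# should this normal be flipped to point landward?
landward_flip <- function(anchor, normal, ocean_mask) {
  if (is.null(ocean_mask)) return(normal[2] < 0)
  C <- ocean_mask$pixel_size
  for (d in C * c(1, 2, 4, 8)) {
    plus <- grid_value_at(ocean_mask, rbind(anchor + d * normal))
    minus <- grid_value_at(ocean_mask, rbind(anchor - d * normal))
    if (!is.na(plus) && !is.na(minus) && plus != minus)
      return(plus == 1)   # ocean on the +normal side -> flip
    if (!is.na(plus) && is.na(minus)) return(plus == 1)
    if (is.na(plus) && !is.na(minus)) return(minus != 1)
  }
  normal[2] < 0
}

#' Sample one transect over a scene
#'
#' Walks the transect landward from its anchor at pixel-size steps (step
#' midpoints, nearest-pixel lookup) and counts the steps landing on
#' mangrove-mask pixels; gaps are excluded, so the implied width
#' `C * N` is the summed length of the mangrove segments the line crosses.
#' Canopy-height and NDVI means are taken over exactly those pixels; nodata
#' pixels and steps outside the raster are skipped.
#'
#' @param scene a `coast_scene`.
#' @param transect one row of the [build_transects()] data.frame (or a list
#'   with `x`, `y`, `dx`, `dy`, `length`).
#' @param ndvi optional precomputed [ndvi_grid()] raster (saves recomputation
#'   across many transects).
#' @return list: `index`, `n` (mangrove pixel count), `mean_height`,
#'   `mean_ndvi` (NA when `n` = 0), `contains` flag.
#' @export
sample_transect <- function(scene, transect, ndvi = NULL) {
  C <- scene$pixel_size
  if (is.null(ndvi)) ndvi <- ndvi_grid(scene)
  nsteps <- floor(transect$length / C)
  t_ <- (seq_len(nsteps) - 0.5) * C
  pts <- cbind(transect$x + t_ * transect$dx,
               transect$y + t_ * transect$dy)
  mk <- grid_value_at(scene$mask, pts)
  hit <- !is.na(mk) & mk == 1
  n <- sum(hit)
  if (n == 0) {
    return(list(index = transect$index %||% NA_integer_, n = 0L,
                mean_height = NA_real_, mean_ndvi = NA_real_,
                contains = FALSE))
  }
  h <- grid_value_at(scene$height, pts[hit, , drop = FALSE])
  v <- grid_value_at(ndvi, pts[hit, , drop = FALSE])
  list(index = transect$index %||% NA_integer_, n = as.integer(n),
       mean_height = mean(h, na.rm = TRUE),
       mean_ndvi = mean(v, na.rm = TRUE),
       contains = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample a set of transects; returns a data.frame
sample_transects <- function(scene, transects, ndvi = NULL) {
  if (is.null(ndvi)) ndvi <- ndvi_grid(scene)
  rows <- lapply(seq_len(nrow(transects)), function(i) {
    s <- sample_transect(scene, as.list(transects[i, ]), ndvi = ndvi)
    data.frame(index = s$index, n = s$n, mean_height = s$mean_height,
               mean_ndvi = s$mean_ndvi, contains = s$contains)
  })
  do.call(rbind, rows)
}

#' Aggregate transect samples into a region record
#'
#' AMW is the mean over transects of `C * N`; ACH and NDVI are means over
#' mangrove-containing transects of the per-transect means (a mean of
#' transect means, not a pooled pixel mean). By default transects containing
#' no mangrove are excluded from all three statistics, so AMW reflects the
#' effective width of the mangrove portions; set `include_empty = TRUE` to
#' let empty transects dilute AMW for sensitivity checks.
#'
#' @param samples data.frame from [sample_transects()].
#' @param region_id,epoch identifiers carried into the record.
#' @param pixel_size the sampling distance `C` in metres.
#' @param include_empty include zero-count transects in the AMW mean?
#' @return one-row data.frame: `region_id`, `epoch`, `amw_m`, `ach_m`,
#'   `ndvi`, `m` (transects), `n` (mangrove-containing transects); or NULL
#'   when no transect contains mangrove (region flagged no-mangrove).
#' @export
aggregate_region <- function(samples, region_id, epoch, pixel_size = 30,
                             include_empty = FALSE) {
  m <- nrow(samples)
  keep <- samples$n > 0
  n <- sum(keep)
  if (n == 0) return(NULL)
  widths <- pixel_size * samples$n
  amw <- if (include_empty) mean(widths) else mean(widths[keep])
  data.frame(region_id = region_id, epoch = epoch,
             amw_m = amw,
             ach_m = mean(samples$mean_height[keep]),
             ndvi = mean(samples$mean_ndvi[keep]),
             m = m, n = n)
}

#' Extract per-region records from a scene
#'
#' Wraps the coastline, casts transects, samples them, and aggregates per
#' region; transects belong to the region containing their anchor. Regions
#' with no mangrove-containing transect are dropped.
#'
#' @param scene a `coast_scene`.
#' @param regions data.frame of rectangular tiles (`region_id`, `xmin`,
#'   `xmax`, `ymin`, `ymax`); defaults to the scene's own tiles.
#' @param spacing transect spacing in metres.
#' @param length transect length in metres.
#' @param tolerance coastline simplification tolerance (metres).
#' @param include_empty passed to [aggregate_region()].
#' @param coastline optional working coastline; computed by
#'   [wrap_coastline()] when NULL.
#' @return data.frame of region records (one row per mangrove region).
#' @export
extract_regions <- function(scene, regions = scene$regions, spacing = 1000,
                            length = 30000, tolerance = NULL,
                            include_empty = FALSE, coastline = NULL) {
  if (is.null(regions) || nrow(regions) == 0)
    stop("configuration error: empty region set")
  if (is.null(tolerance)) tolerance <- scene$pixel_size / 2
  if (is.null(coastline))
    coastline <- wrap_coastline(scene$mask, scene$ocean, tolerance)
  tr <- build_transects(coastline, spacing = spacing, length = length,
                        ocean_mask = scene$ocean)
  ndvi <- ndvi_grid(scene)
  samples <- sample_transects(scene, tr, ndvi = ndvi)
  out <- list()
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    in_r <- tr$x >= r$xmin & tr$x < r$xmax &
      tr$y >= r$ymin & tr$y < r$ymax
    if (!any(in_r)) next
    rec <- aggregate_region(samples[in_r, , drop = FALSE], r$region_id,
                            scene$epoch, pixel_size = scene$pixel_size,
                            include_empty = include_empty)
    if (!is.null(rec)) out[[length(out) + 1L]] <- rec
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
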