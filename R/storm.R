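#' Select severe coast-crossing storms
#'
#' Keeps tracks whose maximum sustained wind strictly exceeds the threshold
#' (64 knots by default, the severe-tropical-storm cutoff) and which
#' geometrically intersect the coastline.
#'
#' @param storms list of `storm_track` objects.
#' @param coastline polyline vertex matrix.
#' @param threshold wind threshold in knots (strict inequality).
#' @return filtered list of storms.
#' @export
select_severe <- function(storms, coastline, threshold = 64) {
  stopifnot(threshold >= 0)
  keep <- vapply(storms, function(s) {
    s$wind_kn > threshold && polylines_intersect(s$track, coastline)
  }, logical(1))
  storms[keep]
}

#' Storm impact zones over mangrove regions
#'
#' Buffers each track by a fixed distance (5 km by default) and collects the
#' mangrove pixels whose centres fall inside the buffer, tagged by the
#' region tile they belong to. A pixel is inside the buffer when its
#' distance to the track polyline is at most the buffer distance.
#'
#' @param storms list of `storm_track` objects.
#' @param scene a `coast_scene` supplying the mangrove mask and regions.
#' @param buffer buffer distance in metres (>= 0).
#' @param regions region tiles; defaults to the scene's.
#' @return list of impact zones: `storm_id`, `buffer`, `region_ids`,
#'   `pixels` (row/col matrix), `pixel_region`.
#' @export
impact_zones <- function(storms, scene, buffer = 5000,
                         regions = scene$regions) {
  if (buffer < 0) stop("geometry error: buffer must be >= 0")
  idx <- which(scene$mask$values == 1, arr.ind = TRUE)
  ctr <- grid_centers(scene$mask, idx)
  region_of <- region_lookup(regions)
  px_region <- region_of(ctr)
  lapply(storms, function(s) {
    d <- distance_to_polyline(ctr, s$track)
    inb <- d <= buffer
    px <- idx[inb, , drop = FALSE]
    pr <- px_region[inb]
    structure(list(storm_id = s$storm_id, buffer = buffer,
                   region_ids = sort(unique(pr[!is.na(pr)])),
                   pixels = px, pixel_region = pr),
              class = "impact_zone")
  })
}

# closure mapping point coordinates to region ids (rectangular tiles)
region_lookup <- function(regions) {
  function(pts) {
    pts <- matrix(pts, ncol = 2L)
    out <- rep(NA_integer_, nrow(pts))
    for (k in seq_len(nrow(regions))) {
      r <- regions[k, ]
      sel <- pts[, 1] >= r$xmin & pts[, 1] < r$xmax &
        pts[, 2] >= r$ymin & pts[, 2] < r$ymax
      out[sel] <- r$region_id
    }
    out
  }
}

#' Before/after NDVI response inside impact zones
#'
#' For each (storm, region) pair with mangrove pixels inside the storm's
#' buffer, computes the mean NDVI over those pixels before and after the
#' event (pixels nodata in either snapshot are excluded pairwise) and pairs
#' the change with the region's pre-storm protection index.
#'
#' @param scene_before,scene_after co-registered `coast_scene` snapshots.
#' @param zones impact zones from [impact_zones()].
#' @param records enriched region records (with `mcpi`) for the pre-storm
#'   epoch.
#' @return data.frame: `region_id`, `storm_id`, `mcpi`, `ndvi_before`,
#'   `ndvi_after`, `delta` (after minus before).
#' @export
ndvi_response <- function(scene_before, scene_after, zones, records) {
  stopifnot_registered(scene_before$mask, scene_after$mask)
  vb <- ndvi_grid(scene_before)$values
  va <- ndvi_grid(scene_after)$values
  out <- list()
  for (z in zones) {
    for (rid in z$region_ids) {
      px <- z$pixels[z$pixel_region == rid, , drop = FALSE]
      b <- vb[px]; a <- va[px]
      ok <- !is.na(b) & !is.na(a)
      if (!any(ok)) {
        warning("zone ", z$storm_id, " region ", rid,
                " has no valid pixel pair; skipped")
        next
      }
      mcpi <- records$mcpi[match(rid, records$region_id)]
      out[[length(out) + 1L]] <- data.frame(
        region_id = rid, storm_id = z$storm_id,
        mcpi = if (length(mcpi)) mcpi else NA_real_,
        ndvi_before = mean(b[ok]), ndvi_after = mean(a[ok]),
        delta = mean(a[ok]) - mean(b[ok]))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Spearman rank correlation with t and exact permutation p-values
#'
#' Tie-corrected Spearman rho: the Pearson correlation of mid-ranks. The
#' default p-value uses the classical t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (two-sided); for small samples (`n` <= 10) an exact permutation p-value —
#' the fraction of the n! rank permutations with `|rho|` at least as large —
#' is available.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact use the exact permutation null? Default `FALSE`; only
#'   allowed for n <= 10.
#' @return list: `rho`, `p`, `n`, `method`. A constant input yields
#'   `rho = NA` with a warning.
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho is undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact permutation p only available for n <= 10")
    perms <- rank_permutations(n)
    # rho is monotone in sum(rx * ry[perm]) for fixed marginals
    mrx <- rx - mean(rx); mry <- ry - mean(ry)
    denom <- sqrt(sum(mrx^2) * sum(mry^2))
    permuted <- matrix(mrx[perms], nrow = nrow(perms))
    stats_all <- abs(as.vector(permuted %*% mry) / denom)
    p <- mean(stats_all >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows)
rank_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- rank_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
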