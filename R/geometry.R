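# Planar polyline geometry. All coordinates are projected metres; a polyline
# is an n x 2 matrix of vertices. No geodesic handling anywhere.

as_polyline <- function(p) {
  p <- matrix(as.numeric(p), ncol = 2L)
  if (nrow(p) < 2L) stop("a polyline needs at least 2 vertices")
  p
}

#' Polyline arc length
#'
#' @param p n x 2 vertex matrix.
#' @return total length in metres.
#' @export
polyline_length <- function(p) {
  p <- as_polyline(p)
  sum(sqrt(rowSums(diff(p)^2)))
}

# cumulative arc length at each vertex
arc_positions <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

#' Point at an arc-length position along a polyline
#'
#' Linear interpolation along segments; positions are clamped to `[0, L]`.
#'
#' @param p n x 2 vertex matrix.
#' @param s arc-length positions (metres), vectorized.
#' @return length(s) x 2 matrix of points.
#' @export
point_along <- function(p, s) {
  p <- as_polyline(p)
  cs <- arc_positions(p)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  x <- stats::approx(cs, p[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cs, p[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}

#' Unit tangent at an arc-length position
#'
#' Estimated as the chord direction between the points at `s - window` and
#' `s + window`, which smooths the piecewise-constant segment tangents of
#' finely sampled curves; near the ends the chord is truncated.
#'
#' @param p n x 2 vertex matrix.
#' @param s arc-length positions (vectorized).
#' @param window half-width of the chord in metres; defaults to the mean
#'   segment length.
#' @return length(s) x 2 matrix of unit tangents.
#' @export
polyline_tangent <- function(p, s, window = NULL) {
  p <- as_polyline(p)
  if (is.null(window)) window <- polyline_length(p) / (nrow(p) - 1L)
  a <- point_along(p, s - window)
  b <- point_along(p, s + window)
  d <- b - a
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0)) stop("degenerate (zero-length) coastline segment")
  d / nrm
}

#' Douglas-Peucker polyline simplification
#'
#' @param p n x 2 vertex matrix.
#' @param tolerance maximum allowed perpendicular deviation (metres) of any
#'   removed vertex from the simplified line; `0` keeps every vertex.
#' @return simplified vertex matrix (endpoints always kept).
#' @export
simplify_polyline <- function(p, tolerance) {
  p <- as_polyline(p)
  if (tolerance <= 0) return(p)
  keep <- rep(FALSE, nrow(p))
  keep[c(1L, nrow(p))] <- TRUE
  stack <- list(c(1L, nrow(p)))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- point_segment_distance(p[mid, , drop = FALSE], p[i, ], p[j, ])
    w <- which.max(d)
    if (d[w] > tolerance) {
      k <- mid[w]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  p[keep, , drop = FALSE]
}

# distance from points (n x 2) to the segment a--b
point_segment_distance <- function(pts, a, b) {
  pts <- matrix(pts, ncol = 2L)
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(colSums((t(pts) - a)^2)))
  t_ <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t_ <- pmin(pmax(t_, 0), 1)
  proj <- cbind(a[1] + t_ * ab[1], a[2] + t_ * ab[2])
  sqrt(rowSums((pts - proj)^2))
}

#' Distance from points to a polyline
#'
#' @param pts n x 2 matrix of points.
#' @param p polyline vertex matrix.
#' @return numeric vector of minimum distances (metres).
#' @export
distance_to_polyline <- function(pts, p) {
  p <- as_polyline(p)
  pts <- matrix(pts, ncol = 2L)
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(p) - 1L)) {
    d <- pmin(d, point_segment_distance(pts, p[i, ], p[i + 1L, ]))
  }
  d
}

# do segments p1--p2 and p3--p4 intersect (inclusive of endpoints)?
segments_intersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c) {
    o(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on_seg(p1, p2, p3) || on_seg(p1, p2, p4) ||
    on_seg(p3, p4, p1) || on_seg(p3, p4, p2)
}

#' Do two polylines intersect?
#'
#' Exact segment-pair test, endpoints inclusive.
#'
#' @param a,b polyline vertex matrices.
#' @return logical.
#' @export
polylines_intersect <- function(a, b) {
  a <- as_polyline(a); b <- as_polyline(b)
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq_len(nrow(b) - 1L)) {
      if (segments_intersect(a[i, ], a[i + 1L, ], b[j, ], b[j + 1L, ]))
        return(TRUE)
    }
  }
  FALSE
}
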