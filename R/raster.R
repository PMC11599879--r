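#' Planar raster grid
#'
#' A minimal single-band raster on a regular planar (projected-metre) grid.
#' Values are stored as a matrix whose rows index the y axis (row 1 at the
#' grid origin, increasing y) and whose columns index x. The geotransform is
#' an origin (the outer corner of pixel `[1, 1]`) plus a square pixel size;
#' pixel centres sit at `origin + (index - 0.5) * pixel_size`.
#'
#' @param values numeric or logical matrix (rows = y, cols = x).
#' @param origin length-2 numeric, planar coordinates (x, y) of the grid's
#'   lower-left corner, in metres.
#' @param pixel_size pixel edge length in metres; must be positive.
#' @param nodata sentinel for missing values.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), pixel_size = 30,
                        nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be length-2 numeric")
  if (is.logical(values)) storage.mode(values) <- "integer"
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad)) stop("raster values must be finite, NA, or the nodata sentinel")
  structure(
    list(values = values, origin = as.numeric(origin),
         pixel_size = as.numeric(pixel_size), nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "raster_grid: %d rows (y) x %d cols (x), pixel %g m, origin (%g, %g)\n",
    d[1], d[2], x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Raster extent
#'
#' @param g a [raster_grid].
#' @return named numeric `(xmin, xmax, ymin, ymax)` in metres.
#' @export
grid_extent <- function(g) {
  d <- dim(g$values)
  c(xmin = g$origin[1], xmax = g$origin[1] + d[2] * g$pixel_size,
    ymin = g$origin[2], ymax = g$origin[2] + d[1] * g$pixel_size)
}

#' Pixel lookup for planar points
#'
#' Maps planar points to (row, col) indices under the half-open pixel
#' convention: pixel `[r, c]` covers `[origin + (c-1)*px, origin + c*px)` in x
#' and likewise in y, so a point on a shared pixel boundary belongs to the
#' pixel on its upper side.
#'
#' @param g a [raster_grid].
#' @param xy n x 2 matrix of planar coordinates.
#' @return n x 2 integer matrix of (row, col); NA where outside the extent.
#' @export
grid_locate <- function(g, xy) {
  xy <- matrix(xy, ncol = 2L)
  d <- dim(g$values)
  col <- floor((xy[, 1] - g$origin[1]) / g$pixel_size) + 1L
  row <- floor((xy[, 2] - g$origin[2]) / g$pixel_size) + 1L
  out <- col < 1L | col > d[2] | row < 1L | row > d[1]
  row[out] <- NA_integer_; col[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Values at planar points
#'
#' @param g a [raster_grid].
#' @param xy n x 2 matrix of planar coordinates.
#' @return numeric vector; NA outside the extent or at nodata pixels.
#' @export
grid_value_at <- function(g, xy) {
  rc <- grid_locate(g, xy)
  v <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  v[ok] <- g$values[cbind(rc[ok, 1], rc[ok, 2])]
  v[!is.na(v) & v == g$nodata] <- NA_real_
  v
}

#' Pixel-centre coordinates
#'
#' @param g a [raster_grid].
#' @param rc n x 2 matrix of (row, col) indices.
#' @return n x 2 matrix of planar (x, y) centres.
#' @export
grid_centers <- function(g, rc) {
  rc <- matrix(rc, ncol = 2L)
  cbind(x = g$origin[1] + (rc[, 2] - 0.5) * g$pixel_size,
        y = g$origin[2] + (rc[, 1] - 0.5) * g$pixel_size)
}

#' Check two rasters share a grid
#'
#' @param a,b [raster_grid] objects.
#' @return `TRUE` if shape, origin and pixel size agree.
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size))
}

stopifnot_registered <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1]) {
    if (!same_grid(gs[[1]], gs[[i]]))
      stop("rasters are not co-registered (mismatched geotransform)")
  }
  invisible(TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols`/`nrows` header then rows from the
#' top of the grid down).
#'
#' @param g a [raster_grid].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(g, path) {
  d <- dim(g$values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2]),
    sprintf("cellsize %.10g", g$pixel_size),
    sprintf("NODATA_value %.10g", as.numeric(g$nodata)))
  v <- g$values
  v[is.na(v)] <- g$nodata
  rows <- apply(v[rev(seq_len(d[1])), , drop = FALSE], 1L,
                function(r) paste(format(r, trim = TRUE, digits = 15),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] (or any ASCII grid).
#' @return a [raster_grid].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  body <- lines[seq.int(i, length(lines))]
  vals <- matrix(
    scan(text = paste(body, collapse = "\n"), quiet = TRUE),
    nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals <- vals[rev(seq_len(hdr$nrows)), , drop = FALSE]
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals[vals == nodata] <- NA_real_
  raster_grid(vals, origin = c(hdr$xllcorner, hdr$yllcorner),
              pixel_size = hdr$cellsize, nodata = nodata)
}
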