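# Plain-text serialization: rasters as ESRI ASCII grids, lines as GeoJSON,
# tables as CSV. Everything written here reads back bit-comparable.

#' Write a scene to a directory
#'
#' One ASCII grid per raster (`mask`, `height`, `red`, `nir`, `ocean`), the
#' coastline as GeoJSON, regions and ground truth as CSV, and a small JSON
#' header with the epoch and pixel size.
#'
#' @param scene a `coast_scene`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("mask", "height", "red", "nir", "ocean")) {
    write_ascii_grid(scene[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  write_geojson_lines(list(list(coords = scene$coastline,
                                properties = list(kind = "coastline"))),
                      file.path(dir, "coastline.geojson"))
  utils::write.csv(scene$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(epoch = scene$epoch,
                            pixel_size = scene$pixel_size),
                       file.path(dir, "scene.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a scene directory
#'
#' @param dir directory written by [write_scene()].
#' @return a `coast_scene` (without the generating config).
#' @export
read_scene <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "scene.json"))
  g <- lapply(c(mask = "mask", height = "height", red = "red",
                nir = "nir", ocean = "ocean"),
              function(nm) read_ascii_grid(file.path(dir, paste0(nm, ".asc"))))
  feats <- read_geojson_lines(file.path(dir, "coastline.geojson"))
  regions <- utils::read.csv(file.path(dir, "regions.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  # masks as integers, NAs to 0
  for (nm in c("mask", "ocean")) {
    v <- g[[nm]]$values
    v[is.na(v)] <- 0
    g[[nm]]$values <- v
  }
  structure(list(epoch = hdr$epoch, mask = g$mask, height = g$height,
                 red = g$red, nir = g$nir, ocean = g$ocean,
                 coastline = feats[[1]]$coords, regions = regions,
                 truth = truth, pixel_size = hdr$pixel_size,
                 config = NULL), class = "coast_scene")
}

# minimal GeoJSON LineString writer/reader (planar coordinates)
write_geojson_lines <- function(features, path) {
  fl <- lapply(features, function(f) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(apply(f$coords, 1L, c,
                                                    simplify = FALSE))),
         properties = f$properties)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = fl),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_geojson_lines <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(p) unlist(p)))
    list(coords = coords, properties = f$properties)
  })
}

#' Write storm tracks as GeoJSON
#'
#' @param storms list of `storm_track` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_storms <- function(storms, path) {
  write_geojson_lines(lapply(storms, function(s) {
    list(coords = s$track,
         properties = list(storm_id = s$storm_id, wind_kn = s$wind_kn,
                           time = s$time))
  }), path)
}

#' Read storm tracks from GeoJSON
#'
#' @param path file written by [write_storms()] (or compatible GeoJSON with
#'   `wind_kn` properties).
#' @return list of `storm_track` objects.
#' @export
read_storms <- function(path) {
  feats <- read_geojson_lines(path)
  lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    structure(list(track = f$coords,
                   wind_kn = as.numeric(f$properties$wind_kn),
                   storm_id = f$properties$storm_id %||%
                     sprintf("storm-%03d", i),
                   time = f$properties$time %||% NA_character_),
              class = "storm_track")
  })
}

#' Read a pipeline run configuration
#'
#' YAML file mirroring the argument blocks of [run_pipeline()].
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
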