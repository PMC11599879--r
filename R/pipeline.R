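#' Demo pipeline configuration
#'
#' A small self-contained run: a 16-region scene with varied band widths,
#' heights and greenness, three epochs with a height-led decline, an
#' 8-cluster exchange analysis and a storm-validation stage. Any block can
#' be overridden by the corresponding argument of [run_pipeline()] or a YAML
#' file with the same structure.
#'
#' @param out output directory.
#' @param seed global seed; per-stage seeds are derived from it by
#'   stage-name hashing, so adding a stage never perturbs earlier stages.
#' @return named configuration list.
#' @export
default_run_config <- function(out = tempfile("mcpi-run-"), seed = 42L) {
  list(
    out = out,
    seed = as.integer(seed),
    epochs = c(2007, 2013, 2019),
    scene = list(
      nx = 480, ny = 120, pixel_size = 30,
      coast = list(type = "straight", y0 = 600),
      region_size_px = 30,
      band_width = rep(c(300, 600, 900, 1500, 2400, 600, 1200, 900), 2),
      heights = rep(c(12, 9, 7, 5, 4, 11, 3, 6), 2),
      ndvi = rep(c(0.8, 0.7, 0.65, 0.6, 0.55, 0.75, 0.5, 0.62), 2),
      fragmentation = 0.05),
    change = list(width = 0.95, height = 0.7, ndvi = 0.97),
    constants = list(rate = 0.29, exponent = 2.55, cap = 10, scale = 1000),
    sampling = list(spacing = 500, length = 30000, include_empty = FALSE),
    trend = list(alpha = 0.05),
    cena = list(k = 8, bootstrap = 25, metric = "oneminus"),
    validation = list(n_storms = 12, buffer = 5000, wind = 64,
                      wind_range = c(40, 130), severity = 0.3,
                      noise_sd = 0.01)
  )
}

# derive a per-stage seed from the global seed and the stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
  as.integer((as.integer(seed) %% 190000L) * 10007L + h)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> sample -> index -> trend -> cena -> validate against
#' one configuration, writing every intermediate as plain text under the
#' configured output directory plus a JSON-lines manifest with a content
#' hash per file. Identical configuration and seed give identical manifest
#' hashes. A stage failure aborts with the stage name and cause.
#'
#' @param config configuration list (see [default_run_config()]) or path to
#'   a YAML file with the same structure.
#' @param quiet suppress progress messages?
#' @return invisibly, a list with the manifest data.frame and the main
#'   in-memory results (`records`, `trends`, `cena`, `validation`).
#' @export
run_pipeline <- function(config = default_run_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  base <- default_run_config()
  config <- utils::modifyList(base, config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] ", stage), ...)
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }

  epochs <- config$epochs
  n_ep <- length(epochs)

  # -- simulate ------------------------------------------------------------
  scenes <- run_stage("simulate", function() {
    say("simulate", "generating ", n_ep, " epoch scene(s)")
    cfg <- do.call(scene_config, c(config$scene, list(epoch = epochs[1])))
    sd <- stage_seed(config$seed, "simulate")
    scs <- vector("list", n_ep)
    for (i in seq_len(n_ep)) {
      frac <- if (n_ep == 1) 0 else (epochs[i] - epochs[1]) /
        (epochs[n_ep] - epochs[1])
      ci <- cfg
      ci$epoch <- epochs[i]
      ci$band_width <- config$scene$band_width * config$change$width^frac
      ci$heights <- config$scene$heights * config$change$height^frac
      ci$ndvi <- pmin(config$scene$ndvi * config$change$ndvi^frac, 0.99)
      scs[[i]] <- generate_scene(ci, seed = sd)
      d <- file.path(out, "scenes", epochs[i])
      write_scene(scs[[i]], d)
      for (f in list.files(d, full.names = TRUE)) note(f)
    }
    scs
  })

  # -- sample --------------------------------------------------------------
  records <- run_stage("sample", function() {
    say("sample", "transect sampling at ", config$sampling$spacing, " m")
    recs <- do.call(rbind, lapply(scenes, function(sc) {
      extract_regions(sc, spacing = config$sampling$spacing,
                      length = config$sampling$length,
                      include_empty = isTRUE(config$sampling$include_empty))
    }))
    utils::write.csv(recs, note(file.path(out, "records.csv")),
                     row.names = FALSE)
    recs
  })

  # -- index ---------------------------------------------------------------
  records <- run_stage("index", function() {
    consts <- do.call(index_constants, config$constants)
    recs <- enrich_records(records, consts)
    utils::write.csv(recs, note(file.path(out, "records_indexed.csv")),
                     row.names = FALSE)
    summ <- do.call(rbind, lapply(c("amw_m", "ach_m", "ndvi", "mcpi"),
      function(v) cbind(measure = v,
                        summarize_distribution(recs[[v]]))))
    utils::write.csv(summ, note(file.path(out, "summary.csv")),
                     row.names = FALSE)
    say("index", "mean MCPI by epoch: ",
        paste(sprintf("%s=%.1f", epochs,
                      tapply(recs$mcpi, recs$epoch, mean)), collapse = ", "))
    recs
  })

  # -- trend ---------------------------------------------------------------
  trends <- run_stage("trend", function() {
    if (n_ep < 3) {
      say("trend", "fewer than 3 epochs; skipping regression")
      return(NULL)
    }
    ids <- sort(unique(records$region_id))
    tr <- do.call(rbind, lapply(ids, function(id) {
      s <- records[records$region_id == id, c("epoch", "amw_m")]
      names(s) <- c("year", "amw_m")
      if (length(unique(s$year)) < 3) return(NULL)
      ft <- fit_width_trend(s, alpha = config$trend$alpha)
      data.frame(region_id = id, slope = ft$slope, p_value = ft$p_value,
                 significant = ft$significant,
                 total_change = ft$total_change,
                 percent_rate = ft$percent_rate)
    }))
    utils::write.csv(tr, note(file.path(out, "trends.csv")),
                     row.names = FALSE)
    say("trend", sum(tr$significant), "/", nrow(tr),
        " regions with a significant width trend")
    tr
  })

  # -- cena ----------------------------------------------------------------
  cena <- run_stage("cena", function() {
    two <- records[records$epoch %in% c(epochs[1], epochs[n_ep]), ]
    common <- intersect(two$region_id[two$epoch == epochs[1]],
                        two$region_id[two$epoch == epochs[n_ep]])
    two <- two[two$region_id %in% common, ]
    X <- normalize_features(two)
    k <- config$cena$k
    model <- cluster_cells(X, k = k,
                           seed = stage_seed(config$seed, "cena"),
                           variant = config$cena$metric)
    M <- bootstrap_membership(X, model, reps = config$cena$bootstrap,
                              seed = stage_seed(config$seed, "cena-boot"))
    labs <- labels_by_epoch(model)
    ex <- exchange_matrix(labs[[1]], labs[[length(labs)]], k = k)
    prof <- cluster_profiles(model, X, two)
    utils::write.csv(data.frame(row = rownames(X), cluster = model$labels),
                     note(file.path(out, "cena_labels.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(M),
                     note(file.path(out, "cena_membership.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(unclass(ex)),
                     note(file.path(out, "cena_exchange.csv")),
                     row.names = FALSE)
    utils::write.csv(exchange_edges(ex),
                     note(file.path(out, "cena_edges.csv")),
                     row.names = FALSE)
    utils::write.csv(prof, note(file.path(out, "cena_profiles.csv")),
                     row.names = FALSE)
    say("cena", "exchange diagonal (stable regions): ",
        sum(diag(unclass(ex))), "/", length(common))
    list(model = model, membership = M, exchange = ex, profiles = prof)
  })

  # -- validate ------------------------------------------------------------
  validation <- run_stage("validate", function() {
    vc <- config$validation
    before <- scenes[[n_ep]]
    storms <- generate_storms(vc$n_storms, before,
                              wind_range = vc$wind_range,
                              seed = stage_seed(config$seed, "validate"))
    write_storms(storms, note(file.path(out, "storms.geojson")))
    coast <- wrap_coastline(before$mask, before$ocean,
                            tolerance = before$pixel_size)
    severe <- select_severe(storms, coast, threshold = vc$wind)
    zones <- impact_zones(severe, before, buffer = vc$buffer)
    recs_b <- records[records$epoch == epochs[n_ep], ]
    after <- damage_scene(before, zones, recs_b, severity = vc$severity,
                          noise_sd = vc$noise_sd,
                          seed = stage_seed(config$seed, "validate-damage"))
    resp <- ndvi_response(before, after, zones, recs_b)
    if (is.null(resp)) {
      say("validate", "no storm responses (no severe storm hit mangroves)")
      return(NULL)
    }
    utils::write.csv(resp, note(file.path(out, "responses.csv")),
                     row.names = FALSE)
    sp <- spearman_rho(resp$mcpi, resp$delta)
    say("validate", sprintf("rho = %.3f, p = %.4g, n = %d",
                            sp$rho, sp$p, sp$n))
    writeLines(sprintf("rho=%.6f p=%.6g n=%d", sp$rho, sp$p, sp$n),
               note(file.path(out, "validation_summary.txt")))
    list(responses = resp, spearman = sp)
  })

  # -- manifest ------------------------------------------------------------
  written <- unique(written)
  manifest <- data.frame(
    file = sub(paste0("^", out, "/?"), "", written),
    md5 = unname(tools::md5sum(written)),
    bytes = file.size(written))
  manifest <- manifest[order(manifest$file), ]
  con <- file(file.path(out, "manifest.jsonl"), "w")
  for (i in seq_len(nrow(manifest))) {
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  close(con)
  say("done", "manifest with ", nrow(manifest), " artifacts at ", out)
  invisible(list(manifest = manifest, records = records, trends = trends,
                 cena = cena, validation = validation, scenes = scenes))
}
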