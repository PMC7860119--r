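# Readers/writers, run configuration and the end-to-end pipeline.

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Counts are rounded, clipped to `[0, 65535]` and stored losslessly as
#' 16-bit pages; a JSON sidecar (`<path>.json`) records the calibration.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  frames <- movie$frames
  nf <- dim(frames)[3]
  pages <- lapply(seq_len(nf), function(t) {
    pmin(pmax(round(frames[, , t]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size_um,
         frame_interval_s = movie$frame_interval_s,
         channel = movie$channel, n_frames = nf),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF movie
#'
#' Pages are returned in acquisition order as counts on their native
#' integer scale. Calibration is merged from the JSON sidecar written by
#' [write_movie()] when present, else from the arguments.
#'
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval_s,channel Calibration used when no
#'   sidecar exists.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size_um = 0.05, frame_interval_s = 0.005,
                       channel = "green") {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      abort(sprintf("cannot read TIFF '%s': %s", path,
                                    conditionMessage(e)))
                    })
  if (!is.list(pages)) pages <- list(pages)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    bad <- which(shp[1, ] != shp[1, 1] | shp[2, ] != shp[2, 1])[1]
    abort(sprintf("page %d has mismatched dimensions", bad))
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um
    frame_interval_s <- meta$frame_interval_s
    channel <- meta$channel
  }
  movie_stack(pages, pixel_size_um, frame_interval_s, channel)
}

run_config_keys <- c(
  "seed", "n_emitters", "emitter_S", "emitter_D",
  "pixel_size_um", "frame_interval_s", "n_frames", "image_shape",
  "psf_sigma_um", "unitary_brightness", "bleach_rate", "read_noise_sd",
  "autofluorescence_level", "background_level",
  "threshold_sd", "link_radius_px", "max_gap",
  "sigma_um", "n_lags", "min_track_length", "ck_window", "channel"
)

#' Run configuration for the end-to-end pipeline
#'
#' A single validated parameter set governing a whole simulate-detect-track-
#' calibrate-quantify run. Unknown keys are rejected.
#'
#' @param ... Named parameters; see `slimquant:::run_config_keys` for the
#'   accepted names. Unset keys take the stage defaults.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  vals <- list(...)
  unknown <- setdiff(names(vals), run_config_keys)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  defaults <- list(seed = 1L, n_emitters = 10L, emitter_S = 1L,
                   emitter_D = 0.1, threshold_sd = 5, link_radius_px = 5,
                   max_gap = 1L, sigma_um = 0.04, n_lags = 5L,
                   min_track_length = 6L, ck_window = 10L,
                   channel = "green")
  out <- utils::modifyList(defaults, vals)
  structure(out, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()`: a validated [run_config()];
#'   `write_run_config()`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Provenance sidecar written next to every pipeline output table.
provenance_record <- function(config, inputs = character()) {
  list(
    tool = "slimquant",
    version = as.character(utils::packageVersion("slimquant")),
    config_hash = rlang::hash(unclass(config)),
    input_hashes = as.list(vapply(inputs, function(f) {
      if (file.exists(f)) rlang::hash(readBin(f, "raw", file.size(f)))
      else NA_character_
    }, character(1))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Run the full Slimfield analysis pipeline on a simulated movie
#'
#' Executes simulate, detect, track, calibrate and quantify in order,
#' writing every table as CSV with a JSON provenance sidecar. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param I1 Optional known unitary brightness; when `NULL` it is
#'   calibrated from the tracked photobleaching traces.
#' @return A list with the in-memory results: `scene`, `spots`, `tracks`,
#'   `calibration`, `stoichiometry`, `diffusion`, and the output paths.
#' @export
run_pipeline <- function(config, out_dir, I1 = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    sim_keys <- intersect(names(config), names(formals(sim_config)))
    cfg <- do.call(sim_config, unclass(config)[sim_keys])
    emitters <- with_seed(config$seed + 1L, {
      th <- runif(config$n_emitters, 0, 2 * pi)
      rr <- sqrt(runif(config$n_emitters, 0, 0.6))
      tibble(
        x_um = cfg$cell_centre_um[1] + rr * cfg$cell_axes_um[1] * cos(th),
        y_um = cfg$cell_centre_um[2] + rr * cfg$cell_axes_um[2] * sin(th),
        S = config$emitter_S, D = config$emitter_D)
    })
    scene <- simulate_slimfield_movie(cfg, emitters, seed = config$seed)
    movie_path <- file.path(out_dir, "movie.tif")
    write_movie(scene$movie, movie_path)

    stage <- "detect"
    spots <- detect_movie_spots(scene$movie,
                                psf_sigma_um = cfg$psf_sigma_um,
                                threshold_sd = config$threshold_sd)
    if (!nrow(spots)) abort("no spots detected")

    stage <- "track"
    tracks <- link_tracks(spots, config$link_radius_px, config$max_gap)

    stage <- "calibrate"
    cal <- if (is.null(I1)) {
      long <- track_summary(tracks)
      keep <- long$track_id[long$n_spots >= 3L * config$ck_window]
      if (!length(keep)) abort("no tracks long enough for calibration")
      estimate_unitary_brightness(
        tracks[tracks$track_id %in% keep, c("track_id", "intensity")],
        window = config$ck_window, channel = config$channel,
        seed = config$seed)
    } else {
      structure(list(I1 = I1, uncertainty = NA_real_, method = "supplied",
                     n_traces = 0L, n_steps = 0L,
                     channel = config$channel),
                class = "unitary_brightness")
    }

    stage <- "quantify"
    stoich <- track_stoichiometries(tracks, cal$I1,
                                    min_length = config$min_track_length)
    diff <- track_diffusion(tracks, cfg$frame_interval_s,
                            sigma_um = config$sigma_um,
                            n_lags = config$n_lags)
    prov <- provenance_record(config, movie_path)
    wr <- function(tb, name) {
      p <- file.path(out_dir, paste0(name, ".csv"))
      write.csv(tb, p, row.names = FALSE)
      jsonlite::write_json(prov, paste0(p, ".json"), auto_unbox = TRUE)
      p
    }
    paths <- c(
      spots = wr(spots, "spots"),
      tracks = wr(tracks, "tracks"),
      stoichiometry = wr(stoich, "stoichiometry"),
      diffusion = wr(diff, "diffusion")
    )
    jsonlite::write_json(
      list(I1 = cal$I1, uncertainty = cal$uncertainty, method = cal$method,
           n_traces = cal$n_traces, channel = cal$channel),
      file.path(out_dir, "calibration.json"), auto_unbox = TRUE,
      digits = NA)
    list(scene = scene, spots = spots, tracks = tracks, calibration = cal,
         stoichiometry = stoich, diffusion = diff, paths = paths)
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  res
}
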