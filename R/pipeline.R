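# Configuration handling and the end-to-end pipeline driver.

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with the input movie path, its physical calibration
#' and optional stage parameters. Required fields: `input`, `um_per_px`,
#' `fps`. Optional: `out_dir`, `seed`, `sigma_um`, `target_fps`,
#' `max_components`, `min_snr`, `neuropil_radius_um`, `neuropil_sd`,
#' `baseline_mode`, `window_s`.
#'
#' @param path path to a YAML file.
#' @return a validated named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  for (req in c("input", "um_per_px", "fps")) {
    if (is.null(cfg[[req]])) {
      stop(sprintf("config error: required field `%s` is missing", req),
           call. = FALSE)
    }
  }
  assert_scalar_pos(cfg$um_per_px, "um_per_px")
  assert_scalar_pos(cfg$fps, "fps")
  defaults <- list(
    out_dir = "boutonscope-out", seed = 1L, sigma_um = 0.2, target_fps = 6,
    max_components = 50, min_snr = 4, neuropil_radius_um = 2,
    neuropil_sd = 2, baseline_mode = "whole", window_s = 15
  )
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  structure(cfg, class = "run_config")
}

#' Run the full bouton-extraction pipeline on one movie
#'
#' Executes registration, spatial filtering, temporal resampling, ROI
#' extraction, trace extraction, neuropil decontamination and baseline
#' normalization, and writes the results plus a machine-readable provenance
#' record to the output directory: `shifts.csv`, `rois.csv` (centres and
#' area metrics), `traces.csv` (per-ROI f_roi / f_neuropil / f_true /
#' baseline / dff / events) and `provenance.json` (all parameters, the seed
#' and package version — sufficient to reproduce the run). Outputs are
#' deterministic given the configuration.
#'
#' @param config a `run_config`, a plain named list with the same fields, or
#'   a path to a YAML file.
#' @return (invisibly) a list with the `roi_set`, the `trace_bundle` (NULL
#'   when no ROI was found), the registration shifts and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed (input: %s): %s",
                   name, config$input, conditionMessage(e)), call. = FALSE)
    })
  }
  movie <- stage("read", read_movie(config$input, config$um_per_px, config$fps))
  reg <- stage("register", register_rigid(movie))
  filt <- stage("filter", spatial_filter(reg$movie, config$sigma_um))
  res <- stage("resample", temporal_resample(filt, config$target_fps))
  rois <- stage("extract", extract_rois(
    res, max_components = config$max_components, min_snr = config$min_snr,
    seed = config$seed
  ))
  bundle <- NULL
  if (n_rois(rois) > 0L) {
    bundle <- stage("traces", trace_bundle(
      res, rois, radius_um = config$neuropil_radius_um,
      sd_multiplier = config$neuropil_sd,
      baseline_mode = config$baseline_mode, window_s = config$window_s
    ))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.csv(reg$shifts, p("shifts.csv"), row.names = FALSE)
  metrics <- if (n_rois(rois) > 0L) {
    dplyr::left_join(rois$centers, roi_area_metrics(rois), by = "roi")
  } else {
    tibble::tibble(roi = integer())
  }
  utils::write.csv(metrics, p("rois.csv"), row.names = FALSE)
  if (!is.null(bundle)) {
    out_tr <- bundle$traces
    out_tr$event <- rois$events[cbind(out_tr$roi, out_tr$frame)]
    utils::write.csv(out_tr, p("traces.csv"), row.names = FALSE)
  }
  prov <- list(
    package = "boutonscope",
    version = as.character(utils::packageVersion("boutonscope")),
    config = unclass(config),
    seed = config$seed,
    n_frames_in = n_frames(movie),
    n_frames_analyzed = n_frames(res),
    n_rois = n_rois(rois),
    r_global = if (!is.null(bundle)) bundle$r_global else NA
  )
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(rois = rois, bundle = bundle, shifts = reg$shifts,
                 paths = vapply(c("shifts.csv", "rois.csv", "traces.csv",
                                  "provenance.json"), p, "")))
}
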