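# End-to-end orchestration: simulate (optional) -> QC -> distances/datasets
# -> candidate fits -> summaries -> report, with a run manifest echoing
# every threshold so a run is reproducible from its output directory alone.

#' Build a pipeline run configuration
#'
#' Defaults reproduce the package's standard analysis settings (HDOP < 3.5,
#' altitude <= 6 km, daylight only, 1 km buffer, 5-min segment gap, >= 10
#' post-operation records per bird, 3-h SCADA grid). Paths may point at a
#' fixture bundle written by [write_fixture_bundle()] or at real exports.
#'
#' @param telemetry,turbines,scada,raster Input file paths (CSV / ESRI
#'   ASCII). Ignored by stages that are toggled off.
#' @param seed Integer seed (used by the simulate stage).
#' @param simulate If `TRUE`, generate the inputs into `outdir/bundle`
#'   first and use them.
#' @param stages Character vector of stages to run, in order, among
#'   `"qc"`, `"dataset"`, `"fit"`, `"summarize"`.
#' @param max_hdop,max_alt,daylight_only,buffer,max_gap,min_records,
#'   rotor_still_threshold Analysis thresholds (see the stage functions).
#' @param sim Optional list of [sim_config()] overrides for the simulate
#'   stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(telemetry = NULL, turbines = NULL, scada = NULL,
                            raster = NULL, seed = 1, simulate = FALSE,
                            stages = c("qc", "dataset", "fit", "summarize"),
                            max_hdop = 3.5, max_alt = 6000,
                            daylight_only = TRUE, buffer = 1000,
                            max_gap = 300, min_records = 10,
                            rotor_still_threshold = 0, sim = list()) {
  structure(list(
    telemetry = telemetry, turbines = turbines, scada = scada,
    raster = raster, seed = as.integer(seed), simulate = simulate,
    stages = stages, max_hdop = max_hdop, max_alt = max_alt,
    daylight_only = daylight_only, buffer = buffer, max_gap = max_gap,
    min_records = min_records,
    rotor_still_threshold = rotor_still_threshold, sim = sim
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages and writes artefacts under `outdir`:
#' QC'd telemetry and QC report, the before/after and after-operation
#' proximity tables with drop accounting, candidate-model delta tables with
#' the selected model per set, distance summaries, and `manifest.json`
#' (config echo, package version, input checksums).
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param outdir Output directory.
#' @return Invisibly, a list of in-memory results (`fixes`, `ba_records`,
#'   `after_records`, `ba_fits`, `after_fits`, `summaries`, paths).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)

  if (isTRUE(config$simulate)) {
    sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    paths <- write_fixture_bundle(sc, file.path(outdir, "bundle"))
    config$telemetry <- paths$telemetry
    config$turbines <- paths$turbines
    config$scada <- paths$scada
    config$raster <- paths$raster
  }
  for (f in c("telemetry", "turbines", "raster")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(sprintf("input `%s` missing or not found: %s", f,
                    config[[f]] %||% "<unset>"))
    }
  }

  turbines <- read_turbines(config$turbines)
  raster <- read_ascii_grid(config$raster)
  status <- if (!is.null(config$scada) && file.exists(config$scada)) {
    read_status(config$scada,
                rotor_still_threshold = config$rotor_still_threshold)
  } else NULL
  fixes <- read_fixes(config$telemetry)

  if ("qc" %in% config$stages) {
    fixes <- qc_filter(fixes, max_hdop = config$max_hdop,
                       max_alt = config$max_alt,
                       daylight_only = config$daylight_only)
    res$qc <- qc_report(fixes)
    jsonlite::write_json(res$qc, file.path(outdir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$fixes <- fixes

  if ("dataset" %in% config$stages) {
    ba <- build_before_after_records(fixes, turbines, raster,
                                     buffer = config$buffer)
    res$ba_records <- ba
    readr::write_csv(ba, file.path(outdir, "before_after_records.csv"),
                     progress = FALSE)

    gsm <- filter(fixes, .data$tag_type == "GSM")
    segs <- build_segments(gsm, max_gap = config$max_gap)
    after <- if (!is.null(status)) {
      build_after_records(segs, turbines, raster, status,
                          buffer = config$buffer)
    } else NULL
    if (!is.null(after)) {
      after <- after %>%
        mutate(phase = "AFTER") %>%
        filter_min_records_per_bird("AFTER", min_n = config$min_records) %>%
        select(-"phase")
      res$after_records <- after
      readr::write_csv(after, file.path(outdir, "after_records.csv"),
                       progress = FALSE)
    }
    drops <- list(before_after = as.list(drop_report(ba)))
    if (!is.null(after)) drops$after <- as.list(attr(res$after_records, "drops"))
    jsonlite::write_json(drops, file.path(outdir, "drop_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("fit" %in% config$stages && !is.null(res$ba_records)) {
    cand <- enumerate_before_after_candidates()
    res$ba_fits <- purrr::map(seq_len(nrow(cand)),
                              ~ fit_lmm(cand[.x, ], res$ba_records))
    dt <- delta_table(res$ba_fits)
    dt$best <- dt$label == select_best(res$ba_fits)
    readr::write_csv(dt, file.path(outdir, "before_after_model_table.csv"),
                     progress = FALSE)
    res$ba_delta <- dt

    if (!is.null(res$after_records) && nrow(res$after_records) > 0) {
      cand2 <- enumerate_after_candidates()
      res$after_fits <- purrr::map(seq_len(nrow(cand2)),
                                   ~ fit_lmm(cand2[.x, ], res$after_records))
      dt2 <- delta_table(res$after_fits)
      dt2$best <- dt2$label == select_best(res$after_fits)
      readr::write_csv(dt2, file.path(outdir, "after_model_table.csv"),
                       progress = FALSE)
      res$after_delta <- dt2
    }
  }

  if ("summarize" %in% config$stages && !is.null(res$ba_records)) {
    res$summaries <- list(
      by_phase = summarize_distances(res$ba_records, .data$phase),
      by_farm_phase = summarize_distances(res$ba_records, .data$farm_id,
                                          .data$phase),
      within_1_diameter = proportion_within_diameters(
        filter(res$ba_records, .data$phase == "AFTER"), k = 1),
      within_2_diameters = proportion_within_diameters(
        filter(res$ba_records, .data$phase == "AFTER"), k = 2)
    )
    if (!is.null(res$after_records) && nrow(res$after_records) > 0) {
      res$summaries$q025_by_farm_blade <- quantile_by_group(
        res$after_records, 0.025, .data$farm_id, .data$blade_status)
    }
    readr::write_csv(res$summaries$by_phase,
                     file.path(outdir, "distance_summaries.csv"),
                     progress = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("turbavoid")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(
      unlist(config[c("telemetry", "turbines", "scada", "raster")],
             use.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$outdir <- outdir
  invisible(res)
}
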