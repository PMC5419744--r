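#' Read and validate a pipeline run configuration
#'
#' Configurations are structured YAML (or JSON) with a root `seed`,
#' `outdir`, and per-stage parameter blocks mirroring [exchange_params()],
#' [photo_params()] and the analysis settings. Unknown stages and missing
#' required keys are reported with their key paths.
#'
#' @param path YAML or JSON config file.
#' @return A validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list built in code.
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) abort("config key `seed` is required")
  check_number(cfg$seed, "seed")
  if (is.null(cfg$outdir)) abort("config key `outdir` is required")
  known <- c("seed", "outdir", "log_level", "exchange", "photo", "frap",
             "invivo", "kymo", "cells", "traj", "stoich", "ccf", "count")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$exchange)) {
    bad <- setdiff(names(cfg$exchange), names(formals(exchange_params)))
    if (length(bad)) abort(sprintf("unknown key(s) under `exchange`: %s",
                                   paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$photo)) {
    bad <- setdiff(names(cfg$photo), names(formals(photo_params)))
    if (length(bad)) abort(sprintf("unknown key(s) under `photo`: %s",
                                   paste(bad, collapse = ", ")))
  }
  structure(cfg, class = c("run_config", "list"))
}

log_stage <- function(level, stage, msg) {
  if (identical(level, "quiet")) return(invisible())
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run a simulation/analysis pipeline from a configuration
#'
#' Executes the requested stages in order, wiring each analysis stage to
#' the outputs of the matching simulation stage. All randomness flows from
#' the root `seed` via per-stage derived streams, so the same config and
#' seed reproduce identical trace files bit for bit. Every output is listed
#' in a manifest with md5 checksums.
#'
#' Stages: `simulate-kymo`, `simulate-frap`, `simulate-invivo`,
#' `simulate-cells`, `analyze-traj`, `analyze-frap`, `analyze-ccf`,
#' `count-cells`.
#'
#' @param config A `run_config` (or bare list, validated on entry).
#' @param stages Character vector of stage names, executed in order.
#' @return The manifest tibble (`stage`, `file`, `md5`), invisibly; files
#'   land under `config$outdir`, the manifest as `manifest.json`.
#' @export
run_pipeline <- function(config, stages) {
  cfg <- validate_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  level <- cfg$log_level %||% "info"
  state <- new.env(parent = emptyenv())
  manifest <- list()
  add <- function(stage, file) {
    manifest[[length(manifest) + 1L]] <<-
      tibble(stage = stage, file = basename(file),
             md5 = unname(tools::md5sum(file)))
  }
  xp <- do.call(exchange_params, cfg$exchange %||% list())
  for (stage in stages) {
    log_stage(level, stage, "start")
    switch(stage,
      "simulate-frap" = {
        fr <- cfg$frap %||% list()
        ph <- do.call(photo_params, modifyList(
          list(power_pulse = 60, pulse_period_s = 25, pulse_duration_s = 1,
               bg_sd = 10), cfg$photo %||% list()))
        traces <- simulate_frap_experiment(
          xp, ph,
          n_replisomes = fr$n_replisomes %||% 23,
          duration = fr$duration %||% 100,
          seed = derive_seed(cfg$seed, stage))
        state$frap_traces <- traces
        f <- file.path(cfg$outdir, "frap_traces.csv")
        write_traces(traces, f); add(stage, f)
      },
      "simulate-kymo" = {
        km <- cfg$kymo %||% list()
        ph <- do.call(photo_params, cfg$photo %||% list())
        traj <- simulate_replication_trajectory(
          seed = derive_seed(cfg$seed, paste0(stage, "-traj")),
          processivity_mean = km$processivity_mean %||% 73000)
        kym <- render_kymograph(traj, ph,
                                seed = derive_seed(cfg$seed, paste0(stage, "-render")))
        state$kymo <- kym
        f <- file.path(cfg$outdir, "kymograph.tif")
        write_kymograph(kym, f); add(stage, f)
      },
      "simulate-invivo" = {
        iv <- cfg$invivo %||% list()
        traces <- simulate_invivo_pair(
          mechanism = iv$mechanism %||% "complex_exchange",
          k_on_frames = iv$k_on_frames %||% 0.01,
          k_off_frames = iv$k_off_frames %||% 0.01,
          n_frames = iv$n_frames %||% 300,
          n_foci = iv$n_foci %||% 300,
          seed = derive_seed(cfg$seed, stage))
        state$invivo_traces <- traces
        f <- file.path(cfg$outdir, "invivo_traces.csv")
        write_traces(traces, f); add(stage, f)
      },
      "simulate-cells" = {
        cl <- cfg$cells %||% list()
        field <- simulate_cell_field(
          n_cells = cl$n_cells %||% 100,
          copies_per_cell = cl$copies_per_cell %||% 104,
          unit_intensity = cl$unit_intensity %||% 158,
          seed = derive_seed(cfg$seed, stage))
        state$cell_field <- field
        f <- file.path(cfg$outdir, "cell_traces.csv")
        readr::write_csv(field$cell_traces, f); add(stage, f)
        f2 <- file.path(cfg$outdir, "cell_truth.json")
        write_result_json(field$cells, f2); add(stage, f2)
      },
      "analyze-traj" = {
        if (is.null(state$kymo)) abort("analyze-traj needs simulate-kymo output")
        traj <- track_fork(state$kymo)
        segs <- segment_trajectory(traj,
                                   min_duration = (cfg$traj %||% list())$min_duration %||% 5)
        f <- file.path(cfg$outdir, "segments.csv")
        readr::write_csv(segs, f); add(stage, f)
      },
      "analyze-frap" = {
        if (is.null(state$frap_traces)) abort("analyze-frap needs simulate-frap output")
        curve <- extract_and_average_recovery(state$frap_traces)
        fit <- fit_exchange_time(curve)
        f <- file.path(cfg$outdir, "recovery_curve.csv")
        readr::write_csv(as_tibble(curve), f); add(stage, f)
        f2 <- file.path(cfg$outdir, "exchange_time.json")
        write_result_json(fit, f2); add(stage, f2)
      },
      "analyze-ccf" = {
        if (is.null(state$invivo_traces)) abort("analyze-ccf needs simulate-invivo output")
        cc <- cfg$ccf %||% list()
        max_lag_s <- cc$max_lag_s %||% 3
        avg <- average_ccf(state$invivo_traces, max_lag_s)
        fit <- fit_ccf_decay(avg)
        f <- file.path(cfg$outdir, "ccf_curve.csv")
        readr::write_csv(as_tibble(avg), f); add(stage, f)
        f2 <- file.path(cfg$outdir, "ccf_fit.json")
        write_result_json(fit, f2); add(stage, f2)
      },
      "count-cells" = {
        if (is.null(state$cell_field)) abort("count-cells needs simulate-cells output")
        ct <- cfg$count %||% list()
        if (is.null(ct$volume_fL)) {
          abort("config key `count.volume_fL` is required for count-cells")
        }
        res <- count_cells(state$cell_field, cell_geometry(ct$volume_fL))
        f <- file.path(cfg$outdir, "cell_records.csv")
        readr::write_csv(res$records, f); add(stage, f)
        f2 <- file.path(cfg$outdir, "count_summary.json")
        write_result_json(res$summary, f2); add(stage, f2)
      },
      abort(sprintf("unknown stage `%s`", stage))
    )
    log_stage(level, stage, "done")
  }
  man <- purrr::list_rbind(manifest)
  jsonlite::write_json(man, file.path(cfg$outdir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Full counting workflow on a simulated (or measured) cell field
#'
#' Fits the coverslip background, corrects and fits every cell trace,
#' detects bleaching steps in the focus traces, calibrates the
#' single-molecule intensity, and converts amplitudes into copies and
#' concentrations.
#'
#' @param field A list shaped like [simulate_cell_field()] output.
#' @param geom A [cell_geometry()].
#' @return List with `records` (per-cell tibble: cell_id, area_px,
#'   mean_intensity, amplitude, copies, conc_nM), `calibration`, and
#'   `summary` (means and the single-molecule unit).
#' @export
count_cells <- function(field, geom = cell_geometry()) {
  bg_fit <- fit_field_background(field$field_trace)
  autofl <- field$cells$autofluorescence
  records <- purrr::map(seq_len(nrow(field$cells)), function(i) {
    tr <- filter(field$cell_traces, .data$cell_id == field$cells$cell_id[i])
    fit <- correct_and_fit_cell(tr, autofl[i], bg_fit)
    tibble(cell_id = field$cells$cell_id[i],
           area_px = field$cells$area_px[i],
           amplitude = fit$amplitude,
           mean_intensity = fit$amplitude / field$cells$area_px[i])
  }) |> purrr::list_rbind()
  steps <- field$focus_traces |>
    group_by(.data$focus_id) |>
    dplyr::group_map(function(tr, key) detect_steps(arrange(tr, .data$frame))$steps) |>
    unlist()
  cal <- single_molecule_intensity(steps)
  records$copies <- vapply(seq_len(nrow(records)), function(i) {
    copy_number(records[i, ], cal)
  }, numeric(1))
  records$conc_nM <- concentration(pmax(records$copies, 0), geom)
  list(
    records = records, calibration = cal, background_fit = bg_fit,
    summary = list(mean_copies = mean(records$copies),
                   mean_conc_nM = mean(records$conc_nM),
                   unit_mean = cal$unit_mean, unit_sem = cal$sem,
                   n_cells = nrow(records), n_steps = length(steps),
                   volume_fL = geom$volume_fL)
  )
}
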