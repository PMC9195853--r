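#' Configuration of an end-to-end simulated experiment
#'
#' Bundles every tunable of the simulate-fit-analyse chain with defaults
#' matching the reference experimental design: 500 ms trains at 90 Hz built from
#' 170 Hz / 40 um pulses sampled at 40 kHz, a 1000 ms gap in gap sessions,
#' 30 repetitions per level in 3 blocks, 25 participants, and a
#' cumulative-Gaussian mixture fit with 16 multistarts. The configuration
#' round-trips losslessly through JSON.
#'
#' @param n_participants Cohort size. Default 25.
#' @param seed Master seed.
#' @param stimulus List of reference-train fields (`waveform_frequency_hz`,
#'   `amplitude_um`, `pulse_rate_hz`, `duration_ms`, `base_indentation_mm`,
#'   `sample_rate_hz`).
#' @param schedule List with `reps_per_level` and `practice`.
#' @param population A [population_spec()] or a plain list of its fields.
#' @param fit List with `sigmoid`, `n_starts`, `gamma_mode`.
#' @param analysis List with `pooling` (`"pooled"` or `"individual"`) and
#'   `overlay_gap` (logical: rescale the gap or no-gap sessions).
#' @return An object of class `run_config` (a nested list).
#' @export
run_config <- function(n_participants = 25,
                       seed = 1,
                       stimulus = list(
                         waveform_frequency_hz = 170, amplitude_um = 40,
                         pulse_rate_hz = 90, duration_ms = 500,
                         base_indentation_mm = 1, sample_rate_hz = 40000
                       ),
                       schedule = list(reps_per_level = 30, practice = FALSE),
                       population = population_spec(),
                       fit = list(
                         sigmoid = "cumulative_gaussian", n_starts = 16,
                         gamma_mode = "reference_point"
                       ),
                       analysis = list(pooling = "pooled", overlay_gap = FALSE)) {
  if (!inherits(population, "population_spec")) {
    population <- do.call(population_spec, population)
  }
  structure(
    list(
      n_participants = n_participants, seed = seed, stimulus = stimulus,
      schedule = schedule, population = population, fit = fit,
      analysis = analysis
    ),
    class = "run_config"
  )
}

config_reference <- function(config) {
  s <- config$stimulus
  train_spec(
    pulse = pulse_spec(s$waveform_frequency_hz, s$amplitude_um),
    pulse_rate_hz = s$pulse_rate_hz,
    duration_ms = s$duration_ms,
    base_indentation_mm = s$base_indentation_mm,
    sample_rate_hz = s$sample_rate_hz
  )
}

#' Run the full simulate-fit-analyse chain
#'
#' Simulates a cohort with [simulate_cohort()], fits every session with
#' [fit_cohort()], and runs the downstream analyses: validity census, paired
#' gap/no-gap comparisons (where at least two valid pairs exist) and the
#' six-formulation intensity overlays. When `out_dir` is given, writes
#' `responses.csv`, `thresholds.csv`, `census.csv`, `comparisons.json`,
#' `intensity_overlays.csv` and a `manifest.json` recording the
#' configuration, its hash and the session trial totals. Deterministic given
#' the configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list with elements `responses`, `thresholds`, `census`,
#'   `comparisons`, `overlays` and `manifest`, invisibly when writing.
#' @export
#' @examples
#' cfg <- run_config(n_participants = 2, schedule = list(
#'   reps_per_level = 3, practice = FALSE
#' ))
#' res <- run_end_to_end(cfg)
#' res$census
run_end_to_end <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  reference <- config_reference(config)
  responses <- simulate_cohort(
    config$n_participants, config$population, seed = config$seed,
    reps_per_level = config$schedule$reps_per_level,
    practice = isTRUE(config$schedule$practice),
    reference = reference
  )
  thresholds <- fit_cohort(
    responses,
    gamma_mode = config$fit$gamma_mode,
    sigmoid = config$fit$sigmoid,
    n_starts = config$fit$n_starts,
    seed = config$seed
  )
  census <- validity_census(thresholds)
  comparisons <- purrr::map_dfr(unique(thresholds$condition), function(cnd) {
    tryCatch(
      compare_gap_nogap(thresholds, cnd),
      error = function(e) tibble::tibble(
        condition = cnd, n_pairs = NA_integer_, dof = NA_integer_,
        t_statistic = NA_real_, p_value = NA_real_, auc = NA_real_,
        pearson_r = NA_real_, mean_diff = NA_real_
      )
    )
  })
  overlays <- intensity_overlays(
    responses,
    gap = isTRUE(config$analysis$overlay_gap),
    mode = config$analysis$pooling,
    n_starts = config$fit$n_starts, seed = config$seed,
    reference = reference
  )

  trial_totals <- responses |>
    dplyr::count(.data$participant_id, .data$condition, .data$gap_ms,
                 name = "n_trials")
  manifest <- list(
    config = unclass_deep(config),
    config_hash = rlang::hash(unclass_deep(config)),
    n_participants = config$n_participants,
    sessions_per_participant = length(unique(paste(
      responses$condition, responses$gap_ms
    ))),
    trial_totals = trial_totals,
    auc_definition = paste(
      "probability of superiority on paired differences:",
      "mean(gap > no-gap) + 0.5 * mean(ties)"
    ),
    r_version = as.character(getRversion())
  )

  result <- list(
    responses = responses, thresholds = thresholds, census = census,
    comparisons = comparisons, overlays = overlays, manifest = manifest
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(responses, file.path(out_dir, "responses.csv"))
    readr::write_csv(thresholds, file.path(out_dir, "thresholds.csv"))
    readr::write_csv(census$census, file.path(out_dir, "census.csv"))
    jsonlite::write_json(
      comparisons, file.path(out_dir, "comparisons.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
    readr::write_csv(overlays, file.path(out_dir, "intensity_overlays.csv"))
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
    return(invisible(result))
  }
  result
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else {
    x
  }
}

#' Serialise or restore a run configuration
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(
    unclass_deep(config), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON stores whole numbers as integers; restore doubles for stability
  x <- rapply(x, as.numeric, classes = "integer", how = "replace")
  run_config(
    n_participants = x$n_participants,
    seed = x$seed,
    stimulus = as.list(x$stimulus),
    schedule = as.list(x$schedule),
    population = as.list(x$population),
    fit = as.list(x$fit),
    analysis = as.list(x$analysis)
  )
}
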