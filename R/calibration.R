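#' Parameter-recovery simulation
#'
#' Repeatedly simulates binomial response data from a known psychometric
#' mixture model at the study design (by default 14 levels x 30 trials) and
#' refits it, returning per-replicate estimates. Used to verify that the
#' maximum-likelihood threshold estimate is recovered with median absolute
#' error well below the psychometric width.
#'
#' @param n_replicates Number of simulated datasets.
#' @param truth A [psychometric_params()] generating the data.
#' @param levels Stimulus levels.
#' @param n_per_level Trials per level.
#' @param seed Master seed.
#' @param n_starts Multistarts per fit.
#' @return A tibble with one row per replicate: `replicate`, `m_hat`,
#'   `w_hat`, `gamma_hat`, `delta_hat`, `valid`, `threshold`.
#' @export
#' @examples
#' rec <- recovery_simulation(
#'   20, psychometric_params(205, 40, 0.1, 0.02), seed = 1, n_starts = 8
#' )
#' median(abs(rec$m_hat - 205))
recovery_simulation <- function(n_replicates,
                                truth = psychometric_params(205, 40, 0.1, 0.02),
                                levels = change_levels("shape"),
                                n_per_level = 30,
                                seed = 1, n_starts = 16) {
  stopifnot(inherits(truth, "psychometric_params"))
  p_true <- predict_psychometric(truth, levels)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    k <- withr::with_seed(
      derive_seed(seed, 11, r),
      rbinom(length(levels), n_per_level, p_true)
    )
    fit <- fit_psychometric(
      binomial_data(levels, rep(n_per_level, length(levels)), k),
      n_starts = n_starts, seed = derive_seed(seed, 12, r)
    )
    tibble::tibble(
      replicate = r,
      m_hat = if (is.null(fit$params)) NA_real_ else fit$params$m,
      w_hat = if (is.null(fit$params)) NA_real_ else fit$params$w,
      gamma_hat = if (is.null(fit$params)) NA_real_ else fit$params$gamma,
      delta_hat = if (is.null(fit$params)) NA_real_ else fit$params$delta,
      valid = fit$valid,
      threshold = fit$threshold_corrected
    )
  })
}

#' Type-I-error simulation for the paired gap/no-gap comparison
#'
#' Simulates cohorts of observers whose gap width inflation is exactly 1 (no
#' working-memory degradation, so the null hypothesis of equal gap and no-gap
#' thresholds is true), runs the shape-change sessions through the fitting
#' pipeline, and applies the paired t-test to the per-participant threshold
#' pairs. Under the null the rejection rate at `alpha` should match `alpha`.
#'
#' The trial schedules are built once and shared across replicates (the trial
#' order does not enter the aggregated counts); only the response draws and
#' observer draws vary.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param n_participants Participants per cohort.
#' @param population A [population_spec()]; its `gap_width_inflation` must
#'   be 1 so the null holds.
#' @param seed Master seed.
#' @param n_starts Multistarts per fit.
#' @param reps_per_level Trials per change level.
#' @return A tibble with one row per replicate: `replicate`, `n_pairs`,
#'   `t_statistic`, `p_value`, `auc`.
#' @export
type1_simulation <- function(n_replicates, n_participants = 8,
                             population = population_spec(),
                             seed = 1, n_starts = 8,
                             reps_per_level = 30) {
  stopifnot(inherits(population, "population_spec"))
  if (population$gap_width_inflation != 1) {
    stop("type-I calibration requires gap_width_inflation = 1 (true null)",
         call. = FALSE)
  }
  sched_nogap <- build_schedule("shape", 0, seed = derive_seed(seed, 21),
                                reps_per_level = reps_per_level)
  sched_gap <- build_schedule("shape", 1000, seed = derive_seed(seed, 22),
                              reps_per_level = reps_per_level)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    records <- purrr::map_dfr(seq_len(n_participants), function(pid) {
      obs <- draw_observer(population, seed = derive_seed(seed, 23, r, pid))
      dplyr::bind_rows(
        simulate_session(obs, sched_nogap,
                         seed = derive_seed(seed, 24, r, pid),
                         participant_id = pid, session = 1L),
        simulate_session(obs, sched_gap,
                         seed = derive_seed(seed, 25, r, pid),
                         participant_id = pid, session = 2L)
      )
    })
    fits <- fit_cohort(records, n_starts = n_starts,
                       seed = derive_seed(seed, 26, r))
    cmp <- tryCatch(
      compare_gap_nogap(fits, "shape"),
      error = function(e) NULL
    )
    if (is.null(cmp)) {
      tibble::tibble(
        replicate = r, n_pairs = NA_integer_, t_statistic = NA_real_,
        p_value = NA_real_, auc = NA_real_
      )
    } else {
      tibble::tibble(
        replicate = r, n_pairs = cmp$n_pairs, t_statistic = cmp$t_statistic,
        p_value = cmp$p_value, auc = cmp$auc
      )
    }
  })
}

#' True corrected threshold of an observer on the native axis
#'
#' Solves, on the native level axis of a condition, for the level at which
#' the observer's false-alarm-corrected response probability crosses 0.5 —
#' the ground truth against which pipeline threshold estimates are compared
#' in end-to-end recovery checks.
#'
#' @param observer An [observer_spec()].
#' @param condition `"shape"` or `"rate"`.
#' @param gap Whether the session has a gap (applies the width inflation).
#' @param reference Reference [train_spec()].
#' @return The native-axis threshold (Hz), or `NA` if the observer's
#'   corrected detection probability never crosses 0.5 in the tested range.
#' @export
observer_true_threshold <- function(observer, condition, gap = FALSE,
                                    reference = train_spec()) {
  stopifnot(inherits(observer, "observer_spec"))
  par <- observer$params
  w_eff <- par$w * if (gap) observer$gap_width_inflation else 1
  par_eff <- psychometric_params(par$m, w_eff, par$gamma, par$delta, par$sigmoid)
  ref_val <- decision_variable(
    reference_level(condition), condition, observer$coding_axis, reference
  )
  prob <- function(level) {
    dv <- decision_variable(level, condition, observer$coding_axis, reference)
    p <- predict_psychometric(par_eff, abs(dv - ref_val))
    false_alarm_correct(p, par$gamma)
  }
  rng <- range(change_levels(condition))
  if (prob(rng[2]) < 0.5 || prob(rng[1]) > 0.5) return(NA_real_)
  uniroot(function(x) prob(x) - 0.5, interval = rng, tol = 1e-8)$root
}
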