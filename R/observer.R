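#' Parametric synthetic observer
#'
#' An observer detects a change by comparing reference and comparison stimuli
#' along a single coding axis: the pulse width (temporally local shape cue),
#' the pulse rate (temporally global cue), or one of the six kinematic
#' intensity formulations. Its probability of reporting a change is the
#' psychometric mixture model evaluated at the absolute difference between
#' the comparison and reference values on that axis; on no-change trials the
#' "yes" probability is the false-alarm rate `gamma`. In gap sessions the
#' psychometric width may be inflated by `gap_width_inflation >= 1`,
#' modelling working-memory degradation (1 = lossless storage).
#'
#' @param coding_axis `"pulse_width_ms"`, `"pulse_rate_hz"`, or
#'   `"intensity:<tag>"` with a tag from [intensity_formulations()].
#' @param params A [psychometric_params()] defined on the absolute-difference
#'   scale of the coding axis (ms for pulse width, Hz for pulse rate,
#'   intensity units otherwise).
#' @param gap_width_inflation Multiplier (>= 1) applied to `w` in sessions
#'   with a gap.
#' @param full_lapse If `TRUE`, lapses flip the response with probability
#'   `delta` on both trial types; by default `delta` only caps the upper
#'   asymptote of change trials, matching the fitted model.
#' @return An object of class `observer_spec`.
#' @export
#' @examples
#' obs <- observer_spec(
#'   "pulse_width_ms",
#'   psychometric_params(m = 0.9, w = 0.9, gamma = 0.06, delta = 0.02)
#' )
observer_spec <- function(coding_axis, params, gap_width_inflation = 1,
                          full_lapse = FALSE) {
  stopifnot(
    is.character(coding_axis), length(coding_axis) == 1,
    inherits(params, "psychometric_params"),
    is.numeric(gap_width_inflation), gap_width_inflation >= 1,
    is.logical(full_lapse)
  )
  valid_axes <- c(
    "pulse_width_ms", "pulse_rate_hz",
    paste0("intensity:", intensity_formulations()$tag)
  )
  if (!coding_axis %in% valid_axes) {
    stop(
      "unknown coding axis: ", coding_axis, " (valid: ",
      paste(valid_axes, collapse = ", "), ")", call. = FALSE
    )
  }
  structure(
    list(
      coding_axis = coding_axis, params = params,
      gap_width_inflation = gap_width_inflation, full_lapse = full_lapse
    ),
    class = "observer_spec"
  )
}

#' Value of a stimulus on an observer's coding axis
#'
#' Maps comparison levels of a condition to the observer's decision axis:
#' pulse width in ms (`1000 / waveform frequency`; constant under rate
#' changes), pulse rate in Hz (constant under shape changes), or a kinematic
#' intensity of the synthesised comparison train. An axis that is constant
#' across a condition's levels is permitted — the observer is then blind to
#' that change type and responds at its false-alarm rate.
#'
#' @param level Comparison level(s) in Hz (waveform frequency for shape,
#'   pulse rate for rate trials).
#' @param condition `"shape"` or `"rate"`.
#' @param axis A coding axis string (see [observer_spec()]).
#' @param reference Reference [train_spec()].
#' @return Numeric axis values, one per level.
#' @export
#' @examples
#' decision_variable(240, "shape", "pulse_width_ms")  # 4.167 ms
decision_variable <- function(level, condition, axis,
                              reference = train_spec()) {
  condition <- match.arg(condition, c("shape", "rate"))
  f_cmp <- if (condition == "shape") level else {
    rep(reference$pulse$waveform_frequency_hz, length(level))
  }
  r_cmp <- if (condition == "rate") level else {
    rep(reference$pulse_rate_hz, length(level))
  }
  if (axis == "pulse_width_ms") {
    1000 / f_cmp
  } else if (axis == "pulse_rate_hz") {
    r_cmp
  } else if (startsWith(axis, "intensity:")) {
    tag <- sub("^intensity:", "", axis)
    uniq <- unique(level)
    vals <- purrr::map_dbl(uniq, function(lv) {
      intensity(make_train(comparison_spec(condition, lv, reference)), tag)
    })
    vals[match(level, uniq)]
  } else {
    stop("unknown coding axis: ", axis, call. = FALSE)
  }
}

observer_yes_prob <- function(observer, schedule, reference = train_spec()) {
  par <- observer$params
  gap <- any(schedule$gap_ms > 0)
  w_eff <- par$w * if (gap) observer$gap_width_inflation else 1
  par_eff <- psychometric_params(par$m, w_eff, par$gamma, par$delta, par$sigmoid)
  condition <- schedule$condition[1]
  ref_val <- decision_variable(
    reference_level(condition), condition, observer$coding_axis, reference
  )
  dv <- decision_variable(
    schedule$level, condition, observer$coding_axis, reference
  )
  delta_axis <- abs(dv - ref_val)
  p <- ifelse(
    schedule$is_change,
    predict_psychometric(par_eff, delta_axis),
    par$gamma
  )
  if (observer$full_lapse) {
    # lapses flip the intended response on both trial types
    base <- ifelse(
      schedule$is_change,
      {
        par_nolapse <- psychometric_params(
          par$m, w_eff, par$gamma, 0, par$sigmoid
        )
        predict_psychometric(par_nolapse, delta_axis)
      },
      par$gamma
    )
    p <- base * (1 - par$delta) + (1 - base) * par$delta
  }
  p
}

#' Simulate one session of a synthetic observer
#'
#' Draws per-trial Yes/No responses for every non-practice trial of a
#' schedule: on change trials `P(yes)` is the observer's psychometric model
#' at the absolute axis difference between comparison and reference (width
#' inflated in gap sessions); on no-change trials `P(yes) = gamma`.
#' Deterministic given `seed`.
#'
#' @param observer An [observer_spec()].
#' @param schedule A schedule tibble from [build_schedule()].
#' @param seed Integer seed for the Bernoulli draws.
#' @param participant_id Identifier copied into the output rows.
#' @param session Session index copied into the output rows.
#' @param reference Reference [train_spec()].
#' @return A response tibble with columns `participant_id`, `session`,
#'   `condition`, `gap_ms`, `trial_index`, `level`, `is_change`,
#'   `response_yes`.
#' @export
#' @examples
#' obs <- observer_spec(
#'   "pulse_width_ms",
#'   psychometric_params(m = 0.9, w = 0.9, gamma = 0.06, delta = 0.02)
#' )
#' resp <- simulate_session(obs, build_schedule("shape", seed = 1), seed = 2)
#' mean(resp$response_yes[!resp$is_change])  # ~ gamma
simulate_session <- function(observer, schedule, seed = 1,
                             participant_id = 1L, session = 1L,
                             reference = train_spec()) {
  stopifnot(inherits(observer, "observer_spec"), is.data.frame(schedule))
  sched <- dplyr::filter(schedule, !.data$practice_flag)
  p <- observer_yes_prob(observer, sched, reference)
  yes <- withr::with_seed(seed, rbinom(nrow(sched), 1L, p) == 1L)
  tibble::tibble(
    participant_id = participant_id,
    session = session,
    condition = sched$condition,
    gap_ms = sched$gap_ms,
    trial_index = sched$trial_index,
    level = sched$level,
    is_change = sched$is_change,
    response_yes = yes
  )
}

#' Observer-population specification
#'
#' Distributional description of a simulated cohort: per-participant
#' threshold `m` and width `w` are drawn from normal distributions (truncated
#' below at small positive values), while `gamma`, `delta` and the gap width
#' inflation are common to all participants.
#'
#' @param coding_axis Coding axis shared by the population.
#' @param m_mean,m_sd Mean and SD of the threshold on the axis-difference
#'   scale.
#' @param w_mean,w_sd Mean and SD of the width.
#' @param gamma,delta Asymptote parameters.
#' @param gap_width_inflation Width multiplier in gap sessions (1 = lossless
#'   memory).
#' @param sigmoid Sigmoid family.
#' @param full_lapse See [observer_spec()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(coding_axis = "pulse_width_ms",
                            m_mean = 0.9, m_sd = 0.25,
                            w_mean = 0.9, w_sd = 0.2,
                            gamma = 0.06, delta = 0.02,
                            gap_width_inflation = 1,
                            sigmoid = c("cumulative_gaussian", "logistic"),
                            full_lapse = FALSE) {
  sigmoid <- match.arg(sigmoid)
  stopifnot(m_mean > 0, w_mean > 0, m_sd >= 0, w_sd >= 0)
  structure(
    list(
      coding_axis = coding_axis, m_mean = m_mean, m_sd = m_sd,
      w_mean = w_mean, w_sd = w_sd, gamma = gamma, delta = delta,
      gap_width_inflation = gap_width_inflation, sigmoid = sigmoid,
      full_lapse = full_lapse
    ),
    class = "population_spec"
  )
}

#' Draw one observer from a population
#'
#' @param population A [population_spec()].
#' @param seed Integer seed.
#' @return An [observer_spec()].
#' @export
draw_observer <- function(population, seed = 1) {
  stopifnot(inherits(population, "population_spec"))
  withr::with_seed(seed, {
    m <- max(rnorm(1, population$m_mean, population$m_sd), population$m_mean / 10)
    w <- max(rnorm(1, population$w_mean, population$w_sd), population$w_mean / 10)
    observer_spec(
      population$coding_axis,
      psychometric_params(
        m, w, population$gamma, population$delta, population$sigmoid
      ),
      gap_width_inflation = population$gap_width_inflation,
      full_lapse = population$full_lapse
    )
  })
}

#' The four experimental sessions
#'
#' @return A tibble with columns `condition` and `gap_ms`: shape/rate crossed
#'   with no-gap/gap (0 or 1000 ms).
#' @export
session_conditions <- function() {
  tidyr::expand_grid(
    condition = c("shape", "rate"),
    gap_ms = c(0, 1000)
  )
}

#' Simulate a cohort performing all four sessions
#'
#' Draws one observer per participant from the population, then simulates the
#' four sessions (shape/rate crossed with gap/no-gap). Session order is
#' counterbalanced over the 24 permutations of the four conditions, assigned
#' to participants cyclically. All randomness derives from `seed`.
#'
#' @param n_participants Number of participants.
#' @param population A [population_spec()].
#' @param seed Integer master seed.
#' @param conditions Sessions to run; defaults to [session_conditions()].
#' @param reps_per_level,practice Passed to [build_schedule()].
#' @param reference Reference [train_spec()].
#' @return A response tibble (one row per non-practice trial of every
#'   session) with the columns of [simulate_session()].
#' @export
#' @examples
#' resp <- simulate_cohort(2, population_spec(), seed = 11, reps_per_level = 3)
#' dplyr::count(resp, participant_id, condition, gap_ms)
simulate_cohort <- function(n_participants, population = population_spec(),
                            seed = 1, conditions = session_conditions(),
                            reps_per_level = 30, practice = FALSE,
                            reference = train_spec()) {
  stopifnot(n_participants >= 1)
  n_cond <- nrow(conditions)
  orders <- all_permutations(n_cond)
  purrr::map_dfr(seq_len(n_participants), function(pid) {
    obs <- draw_observer(population, seed = derive_seed(seed, 1, pid))
    ord <- orders[[(pid - 1) %% length(orders) + 1]]
    purrr::map_dfr(seq_len(n_cond), function(s) {
      cond <- conditions[ord[s], ]
      sched <- build_schedule(
        cond$condition, cond$gap_ms,
        seed = derive_seed(seed, 2, pid, s),
        reps_per_level = reps_per_level, practice = practice
      )
      simulate_session(
        obs, sched,
        seed = derive_seed(seed, 3, pid, s),
        participant_id = pid, session = s, reference = reference
      )
    })
  })
}

# Mix a master seed with stream indices into a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed)
  for (i in idx) x <- (x * 69069 + as.numeric(i) * 12345 + 1) %% 2147483647
  as.integer(x)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Write or read a response table CSV
#'
#' @param responses A response tibble.
#' @param path File path.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   the response tibble.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_integer(),
      session = readr::col_integer(),
      condition = readr::col_character(),
      gap_ms = readr::col_double(),
      trial_index = readr::col_integer(),
      level = readr::col_double(),
      is_change = readr::col_logical(),
      response_yes = readr::col_logical()
    )
  )
}
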