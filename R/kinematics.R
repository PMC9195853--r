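#' The six temporally global intensity formulations
#'
#' Intensity of a pulsatile stimulus is formulated as the time-mean, over the
#' entire stimulus duration (rest periods included), of the absolute velocity
#' or absolute acceleration of the indentation trajectory raised to the power
#' 1, 2 or 3.
#'
#' @return A tibble with columns `tag`, `signal` (`"velocity"` or
#'   `"acceleration"`), `power` and `units`.
#' @export
#' @examples
#' intensity_formulations()
intensity_formulations <- function() {
  tibble::tibble(
    tag = c(
      "mean_abs_v", "mean_sq_v", "mean_abs_v_cubed",
      "mean_abs_a", "mean_sq_a", "mean_abs_a_cubed"
    ),
    signal = rep(c("velocity", "acceleration"), each = 3),
    power = rep(1:3, 2),
    units = c(
      "um/s", "um^2/s^2", "um^3/s^3",
      "um/s^2", "um^2/s^4", "um^3/s^6"
    )
  )
}

#' Velocity and acceleration of a waveform
#'
#' Finite-difference kinematics of the indentation trajectory: central
#' differences in the interior, one-sided at the ends (so the output has the
#' same length as the input). Acceleration is the velocity operator applied
#' twice.
#'
#' @param w A waveform tibble (see [make_train()]) with at least 3 samples.
#' @return A tibble with columns `time_s` and `value` (um/s for velocity,
#'   um/s^2 for acceleration).
#' @export
#' @examples
#' w <- make_pulse(pulse_spec(170, 40), 40000)
#' max(abs(wf_velocity(w)$value))  # ~ 2*pi*170*40 um/s
wf_velocity <- function(w) {
  stopifnot(is.data.frame(w), "displacement_um" %in% names(w))
  if (nrow(w) < 3) stop("need at least 3 samples", call. = FALSE)
  fs <- sample_rate(w)
  tibble::tibble(
    time_s = w$time_s,
    value = pracma::gradient(w$displacement_um, 1 / fs)
  )
}

#' @rdname wf_velocity
#' @export
wf_acceleration <- function(w) {
  v <- wf_velocity(w)
  fs <- sample_rate(w)
  tibble::tibble(
    time_s = v$time_s,
    value = pracma::gradient(v$value, 1 / fs)
  )
}

#' Intensity of a stimulus waveform
#'
#' Computes one of the six kinematic intensity formulations over the whole
#' waveform: `mean(|v|^p)` or `mean(|a|^p)` with p in 1..3. The canonical
#' statistic is the time-mean; `statistic = "sum"` returns the summed variant
#' (mean times the number of samples), which differs only by a constant
#' factor within a fixed design.
#'
#' @param w A waveform tibble spanning the full stimulus.
#' @param formulation One of the tags in [intensity_formulations()].
#' @param statistic `"mean"` (default) or `"sum"`.
#' @return A single non-negative number.
#' @export
#' @examples
#' w <- make_train(train_spec())
#' intensity(w, "mean_abs_v")  # ~ 45 * 4 * 40 / 0.5 = 14400 um/s
intensity <- function(w, formulation, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  forms <- intensity_formulations()
  if (!formulation %in% forms$tag) {
    stop(
      "unknown intensity formulation: ", formulation,
      " (see intensity_formulations())", call. = FALSE
    )
  }
  row <- forms[forms$tag == formulation, ]
  series <- if (row$signal == "velocity") wf_velocity(w) else wf_acceleration(w)
  vals <- abs(series$value)^row$power
  if (statistic == "mean") mean(vals) else sum(vals)
}

#' All six intensities of a waveform
#'
#' @inheritParams intensity
#' @return A tibble with columns `formulation`, `value`, `units`.
#' @export
intensity_profile <- function(w, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  forms <- intensity_formulations()
  tibble::tibble(
    formulation = forms$tag,
    value = purrr::map_dbl(forms$tag, ~ intensity(w, .x, statistic)),
    units = forms$units
  )
}

#' Intensity table over the levels of a condition
#'
#' Maps each comparison level of a condition (plus the reference) to its six
#' intensity values, synthesising the comparison train for each level.
#'
#' @param condition `"shape"` or `"rate"`.
#' @param levels Comparison levels (Hz); defaults to the condition's change
#'   levels plus the reference.
#' @param reference Reference [train_spec()].
#' @param statistic `"mean"` or `"sum"`.
#' @return A tibble with columns `condition`, `level`, `formulation`,
#'   `value`, `units`.
#' @export
intensity_table <- function(condition,
                            levels = NULL,
                            reference = train_spec(),
                            statistic = c("mean", "sum")) {
  condition <- match.arg(condition, c("shape", "rate"))
  statistic <- match.arg(statistic)
  if (is.null(levels)) {
    levels <- sort(c(reference_level(condition), change_levels(condition)))
  }
  purrr::map_dfr(levels, function(lv) {
    w <- make_train(comparison_spec(condition, lv, reference))
    dplyr::mutate(
      intensity_profile(w, statistic),
      condition = condition, level = lv, .before = 1
    )
  })
}

#' Iso-feature deviation of a stimulus family
#'
#' For a family of pulse trains, measures how far a given intensity
#' formulation is from being constant across the family: the maximum relative
#' deviation of the per-member intensity from the family mean. The
#' shape-change family (waveform frequency 170-240 Hz at a fixed 90 Hz rate)
#' lies on an iso-feature line of mean speed, so its deviation under
#' `mean_abs_v` is below 0.5% (discretisation of pulse boundaries prevents
#' exact equality).
#'
#' @param family A list of [train_spec()] objects.
#' @param formulation One of the tags in [intensity_formulations()].
#' @return Max relative deviation (non-negative scalar; 0 for a single-member
#'   family).
#' @export
#' @examples
#' fam <- lapply(c(170, change_levels("shape")), function(f) {
#'   comparison_spec("shape", f)
#' })
#' iso_feature_deviation(fam, "mean_abs_v")  # < 0.005
iso_feature_deviation <- function(family, formulation) {
  stopifnot(is.list(family), length(family) >= 1)
  vals <- purrr::map_dbl(family, ~ intensity(make_train(.x), formulation))
  max(abs(vals - mean(vals))) / mean(vals)
}

#' Closed-form intensities of an ideal pulse train
#'
#' Analytic values of the velocity formulations for a train of `n` raised-
#' cosine pulses `A(1 - cos(2 pi f t))` in a window of `duration_s`:
#' the path length of one pulse is `4A`, so `mean|v| = 4An/D`; one pulse
#' integrates `v^2` to `(2 pi f A)^2 / (2 f)`, giving
#' `mean v^2 = 2 pi^2 f A^2 n / D`. Used as oracles for the sampled
#' kinematics.
#'
#' @param formulation `"mean_abs_v"` or `"mean_sq_v"`.
#' @param f Waveform frequency (Hz).
#' @param a Amplitude (um).
#' @param rate Pulse rate (Hz).
#' @param duration_s Stimulus duration (s).
#' @return The analytic intensity value.
#' @export
intensity_closed_form <- function(formulation, f, a, rate, duration_s) {
  n <- floor(rate * duration_s + 1e-9)
  switch(formulation,
    mean_abs_v = 4 * a * n / duration_s,
    mean_sq_v = 2 * pi^2 * f * a^2 * n / duration_s,
    stop("no closed form implemented for ", formulation, call. = FALSE)
  )
}
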