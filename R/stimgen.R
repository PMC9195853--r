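#' Pulse specification
#'
#' Describes a single indentation pulse: one period of a raised-cosine
#' ("single-period sinusoid") cut from a sinusoid of frequency
#' `waveform_frequency_hz` and amplitude `amplitude_um`. The pulse displaces
#' the skin from the base indentation towards deeper positions and returns,
#' so its temporal width is `1 / waveform_frequency_hz` seconds and its peak
#' excursion is `2 * amplitude_um` (the sinusoid is offset so its minimum
#' sits at the base).
#'
#' @param waveform_frequency_hz Positive frequency (Hz) of the sinusoid the
#'   pulse is cut from. Default 170 Hz, the reference pulse.
#' @param amplitude_um Positive sinusoid amplitude in micrometres. Default
#'   40 um (peak excursion 80 um).
#' @return An object of class `pulse_spec`.
#' @seealso [make_pulse()], [train_spec()]
#' @export
#' @examples
#' ps <- pulse_spec(170, 40)
#' pulse_width_ms(ps)
pulse_spec <- function(waveform_frequency_hz = 170, amplitude_um = 40) {
  stopifnot(
    is.numeric(waveform_frequency_hz), length(waveform_frequency_hz) == 1,
    waveform_frequency_hz > 0,
    is.numeric(amplitude_um), length(amplitude_um) == 1, amplitude_um > 0
  )
  structure(
    list(
      waveform_frequency_hz = waveform_frequency_hz,
      amplitude_um = amplitude_um
    ),
    class = "pulse_spec"
  )
}

#' Pulse width implied by a waveform frequency
#'
#' The width of a single-period pulse is the period of the sinusoid it is cut
#' from: `1000 / waveform_frequency_hz` milliseconds (5.882 ms at 170 Hz,
#' 4.167 ms at 240 Hz).
#'
#' @param x A `pulse_spec`, or a numeric vector of waveform frequencies (Hz).
#' @return Pulse width(s) in milliseconds.
#' @export
pulse_width_ms <- function(x) {
  f <- if (inherits(x, "pulse_spec")) x$waveform_frequency_hz else x
  stopifnot(is.numeric(f), all(f > 0))
  1000 / f
}

#' Pulse-train specification
#'
#' A pulsatile stimulus: `pulse` repeated at `pulse_rate_hz` for
#' `duration_ms`, with rest (no movement relative to the base indentation)
#' between pulses. The pulse must fit inside the inter-pulse period, i.e.
#' `pulse_rate_hz <= waveform_frequency_hz`.
#'
#' @param pulse A [pulse_spec()].
#' @param pulse_rate_hz Pulses per second. Default 90 Hz (the reference).
#' @param duration_ms Train duration in ms. Default 500 ms.
#' @param base_indentation_mm Static indentation the pulses set off from;
#'   stored for bookkeeping, samples are expressed relative to it. Default 1.
#' @param sample_rate_hz Sampling rate in Hz. Default 40000.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(pulse = pulse_spec(),
                       pulse_rate_hz = 90,
                       duration_ms = 500,
                       base_indentation_mm = 1,
                       sample_rate_hz = 40000) {
  stopifnot(
    inherits(pulse, "pulse_spec"),
    is.numeric(pulse_rate_hz), length(pulse_rate_hz) == 1, pulse_rate_hz > 0,
    is.numeric(duration_ms), length(duration_ms) == 1, duration_ms > 0,
    is.numeric(base_indentation_mm), length(base_indentation_mm) == 1,
    is.numeric(sample_rate_hz), length(sample_rate_hz) == 1,
    sample_rate_hz == as.integer(sample_rate_hz), sample_rate_hz > 0
  )
  if (pulse_rate_hz > pulse$waveform_frequency_hz) {
    stop(
      "pulse width (1/", pulse$waveform_frequency_hz,
      " s) exceeds the inter-pulse period (1/", pulse_rate_hz,
      " s): pulses would overlap",
      call. = FALSE
    )
  }
  structure(
    list(
      pulse = pulse,
      pulse_rate_hz = pulse_rate_hz,
      duration_ms = duration_ms,
      base_indentation_mm = base_indentation_mm,
      sample_rate_hz = sample_rate_hz
    ),
    class = "train_spec"
  )
}

new_waveform <- function(samples, sample_rate_hz) {
  out <- tibble::tibble(
    time_s = (seq_along(samples) - 1) / sample_rate_hz,
    displacement_um = samples
  )
  attr(out, "sample_rate_hz") <- sample_rate_hz
  class(out) <- c("tact_waveform", class(out))
  out
}

#' Sampling rate of a waveform
#'
#' @param w A waveform tibble produced by [make_pulse()], [make_train()] or
#'   [make_trial_waveform()].
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(w) {
  sr <- attr(w, "sample_rate_hz")
  if (is.null(sr)) {
    stopifnot(is.data.frame(w), "time_s" %in% names(w), nrow(w) >= 2)
    sr <- round(1 / (w$time_s[2] - w$time_s[1]))
  }
  sr
}

#' Synthesise a single indentation pulse
#'
#' Samples the raised-cosine pulse `p(t) = A * (1 - cos(2 * pi * f * t))` on
#' `t in [0, 1/f)` at `sample_rate_hz`. The pulse occupies
#' `floor(sample_rate_hz / f)` samples; the final sample is the first rest
#' sample and is exactly zero, so a train built from these pulses never
#' overlaps at the highest admissible rate.
#'
#' @param spec A [pulse_spec()].
#' @param sample_rate_hz Sampling rate (Hz); must be at least twice the
#'   waveform frequency (Nyquist).
#' @return A waveform tibble with columns `time_s` and `displacement_um`
#'   (micrometres relative to the base indentation).
#' @export
#' @examples
#' w <- make_pulse(pulse_spec(170, 40), 40000)
#' nrow(w)             # floor(40000 / 170) = 235 samples
#' max(w$displacement_um)  # ~ 2 * 40 = 80 um at mid-pulse
make_pulse <- function(spec, sample_rate_hz = 40000) {
  stopifnot(inherits(spec, "pulse_spec"))
  f <- spec$waveform_frequency_hz
  a <- spec$amplitude_um
  if (sample_rate_hz < 2 * f) {
    stop(
      "sample_rate_hz = ", sample_rate_hz, " is below the Nyquist rate of a ",
      f, " Hz waveform", call. = FALSE
    )
  }
  n <- floor(sample_rate_hz / f)
  t <- (seq_len(n) - 1) / sample_rate_hz
  p <- a * (1 - cos(2 * pi * f * t))
  p[n] <- 0 # first rest sample
  new_waveform(p, sample_rate_hz)
}

pulse_samples <- function(spec, sample_rate_hz) {
  make_pulse(spec, sample_rate_hz)$displacement_um
}

#' Synthesise a pulse train
#'
#' Places `floor(pulse_rate_hz * duration_s)` pulses with pulse `k` (0-based)
#' starting at time `k / pulse_rate_hz`, separated by rest at the base
#' indentation, over a total of `duration_ms` of signal.
#'
#' @param spec A [train_spec()].
#' @return A waveform tibble (see [make_pulse()]).
#' @export
#' @examples
#' w <- make_train(train_spec())  # 90 Hz, 500 ms reference train
#' # 45 pulses:
#' sum(diff(c(0, as.integer(w$displacement_um > 0))) == 1)
make_train <- function(spec) {
  stopifnot(inherits(spec, "train_spec"))
  fs <- spec$sample_rate_hz
  dur_s <- spec$duration_ms / 1000
  n_total <- round(fs * dur_s)
  n_pulses <- floor(spec$pulse_rate_hz * dur_s + 1e-9)
  p <- pulse_samples(spec$pulse, fs)
  out <- numeric(n_total)
  onsets <- round((seq_len(n_pulses) - 1) / spec$pulse_rate_hz * fs)
  for (o in onsets) {
    idx <- (o + 1):min(o + length(p), n_total)
    out[idx] <- p[seq_along(idx)]
  }
  new_waveform(out, fs)
}

#' Synthesise the full stimulus of one trial
#'
#' Concatenates the reference train, an optional stimulus-free gap (the
#' stimulator holds the base indentation), and the comparison train. The
#' comparison differs from the reference only in the parameter selected by
#' `condition`: the pulse waveform frequency for `"shape"` (pulse-width
#' change) or the pulse rate for `"rate"`. On a no-change trial `level`
#' equals the reference value and the two halves are identical.
#'
#' @param condition `"shape"` or `"rate"`.
#' @param level Comparison level: waveform frequency (Hz) for shape, pulse
#'   rate (Hz) for rate.
#' @param gap_ms Gap duration in ms (0 for seamless presentation, 1000 in the
#'   gap condition).
#' @param reference Reference [train_spec()].
#' @return A waveform tibble spanning reference + gap + comparison.
#' @export
make_trial_waveform <- function(condition, level, gap_ms = 0,
                                reference = train_spec()) {
  condition <- match.arg(condition, c("shape", "rate"))
  stopifnot(is.numeric(level), length(level) == 1, level > 0,
            is.numeric(gap_ms), gap_ms >= 0)
  comparison <- comparison_spec(condition, level, reference)
  fs <- reference$sample_rate_hz
  ref_w <- make_train(reference)$displacement_um
  cmp_w <- make_train(comparison)$displacement_um
  gap <- numeric(round(gap_ms / 1000 * fs))
  new_waveform(c(ref_w, gap, cmp_w), fs)
}

#' Comparison-train specification for a trial level
#'
#' @inheritParams make_trial_waveform
#' @return A [train_spec()] identical to `reference` except in the field
#'   selected by `condition`.
#' @export
comparison_spec <- function(condition, level, reference = train_spec()) {
  condition <- match.arg(condition, c("shape", "rate"))
  if (condition == "shape") {
    train_spec(
      pulse = pulse_spec(level, reference$pulse$amplitude_um),
      pulse_rate_hz = reference$pulse_rate_hz,
      duration_ms = reference$duration_ms,
      base_indentation_mm = reference$base_indentation_mm,
      sample_rate_hz = reference$sample_rate_hz
    )
  } else {
    train_spec(
      pulse = reference$pulse,
      pulse_rate_hz = level,
      duration_ms = reference$duration_ms,
      base_indentation_mm = reference$base_indentation_mm,
      sample_rate_hz = reference$sample_rate_hz
    )
  }
}

#' Recover pulses from a synthesised waveform
#'
#' Utility for validating synthesis: detects pulses as maximal runs of
#' strictly positive samples and estimates each pulse's width as the span
#' between the zero samples bracketing the run.
#'
#' @param w A waveform tibble.
#' @return A tibble with one row per detected pulse: `onset_s` (time of the
#'   zero sample the pulse sets off from), `width_ms` and `peak_um`.
#' @export
reconstruct_pulses <- function(w) {
  stopifnot(is.data.frame(w), "displacement_um" %in% names(w))
  fs <- sample_rate(w)
  pos <- w$displacement_um > 0
  d <- diff(c(FALSE, pos, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1
  tibble::tibble(
    onset_s = (starts - 2) / fs, # zero sample preceding the run
    width_ms = (ends - starts + 3) / fs * 1000,
    peak_um = purrr::map2_dbl(starts, ends, ~ max(w$displacement_um[.x:.y]))
  )
}

#' Write a waveform to CSV
#'
#' @param w A waveform tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  readr::write_csv(dplyr::select(w, "time_s", "displacement_um"), path)
  invisible(path)
}
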