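# Shared fixtures: the reference stimulus and a competent width-coding
# observer used across the simulation tests.

ref_train <- function() train_spec() # 90 Hz rate, 170 Hz / 40 um pulses, 500 ms

width_observer <- function(gamma = 0.06, delta = 0.02, inflation = 1) {
  observer_spec(
    "pulse_width_ms",
    psychometric_params(m = 0.9, w = 0.9, gamma = gamma, delta = delta),
    gap_width_inflation = inflation
  )
}

rate_observer <- function(gamma = 0.06, delta = 0.02) {
  observer_spec(
    "pulse_rate_hz",
    psychometric_params(m = 20, w = 18, gamma = gamma, delta = delta)
  )
}

# wrap a bare sample vector as a waveform tibble (40 kHz)
new_wf <- function(samples, fs = 40000) {
  tibble::tibble(
    time_s = (seq_along(samples) - 1) / fs,
    displacement_um = samples
  )
}

# count strictly positive runs in a sampled waveform (independent of
# reconstruct_pulses)
count_pulse_runs <- function(w) {
  pos <- w$displacement_um > 0
  sum(diff(c(FALSE, pos)) == 1)
}
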