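test_that("single pulses follow the raised-cosine closed form", {
  fs <- 40000
  w <- make_pulse(pulse_spec(170, 40), fs)

  # floor(fs/f) samples, zero endpoints, peak 2A at mid-pulse
  expect_equal(nrow(w), floor(fs / 170))
  expect_identical(w$displacement_um[1], 0)
  expect_identical(w$displacement_um[nrow(w)], 0)
  expect_lt(abs(max(w$displacement_um) - 80), 0.01)
  expect_true(all(w$displacement_um >= 0))

  # interior samples match A(1 - cos(2 pi f t)) exactly
  k <- seq_len(nrow(w) - 1)
  expect_equal(
    w$displacement_um[k],
    40 * (1 - cos(2 * pi * 170 * (k - 1) / fs)),
    tolerance = 1e-12
  )
})

test_that("pulse widths are the waveform-frequency period", {
  expect_equal(round(pulse_width_ms(170), 3), 5.882)
  expect_equal(round(pulse_width_ms(240), 3), 4.167)
  expect_equal(pulse_width_ms(pulse_spec(200, 40)), 5)
})

test_that("sub-Nyquist sampling and bad specs are rejected", {
  expect_error(make_pulse(pulse_spec(170, 40), 300), "Nyquist")
  expect_error(pulse_spec(-1, 40))
  expect_error(pulse_spec(170, 0))
  expect_error(train_spec(pulse = pulse_spec(80, 40), pulse_rate_hz = 90),
               "overlap")
})

test_that("trains hold floor(rate x duration) pulses with rest between", {
  w <- make_train(train_spec())
  expect_equal(nrow(w), 20000) # 500 ms at 40 kHz
  expect_equal(count_pulse_runs(w), 45)

  # rest per cycle: inter-onset interval minus pulse width ~ 1/90 - 1/170 s
  rp <- reconstruct_pulses(w)
  onset_gap <- diff(rp$onset_s)
  rest_ms <- mean(onset_gap) * 1000 - mean(rp$width_ms)
  expect_equal(rest_ms, (1 / 90 - 1 / 170) * 1000, tolerance = 0.01)

  # pulse-count law over a design grid
  for (rate in seq(90, 135, by = 15)) {
    for (dur in c(100, 250, 500)) {
      spec <- train_spec(pulse_rate_hz = rate, duration_ms = dur)
      expect_equal(
        count_pulse_runs(make_train(spec)),
        floor(rate * dur / 1000),
        info = paste("rate", rate, "dur", dur)
      )
    }
  }

  # duration of exactly one cycle yields exactly one pulse
  one <- make_train(train_spec(pulse_rate_hz = 90, duration_ms = 1000 / 90))
  expect_equal(count_pulse_runs(one), 1)
})

test_that("waveform steps stay below the analytic slope bound", {
  for (f in c(170, 200, 240)) {
    w <- make_train(train_spec(pulse = pulse_spec(f, 40)))
    max_step <- max(abs(diff(w$displacement_um)))
    expect_lt(max_step, 2 * pi * f * 40 / 40000 * 1.01)
  }
})

test_that("peak detection recovers pulse count and width to within a sample", {
  fs <- 40000
  for (f in c(170, 200, 240)) {
    w <- make_train(train_spec(pulse = pulse_spec(f, 40)))
    rp <- reconstruct_pulses(w)
    expect_equal(nrow(rp), 45)
    expect_true(all(abs(rp$width_ms - 1000 / f) <= 1000 / fs))
    expect_true(all(abs(rp$peak_um - 80) < 0.1))
  }
})

test_that("trial waveforms concatenate reference, gap and comparison", {
  ref <- ref_train()
  nogap <- make_trial_waveform("shape", 200, gap_ms = 0, reference = ref)
  expect_equal(nrow(nogap), 40000) # 500 + 500 ms, seamless

  gap <- make_trial_waveform("shape", 200, gap_ms = 1000, reference = ref)
  expect_equal(nrow(gap), 80000) # 500 + 1000 + 500 ms
  expect_true(all(gap$displacement_um[20001:60000] == 0))

  # no-change trial: second half identical to the first
  nochg <- make_trial_waveform("rate", 90, gap_ms = 0, reference = ref)
  expect_identical(
    nochg$displacement_um[1:20000],
    nochg$displacement_um[20001:40000]
  )

  # comparison differs from reference only in the condition's field
  rate_tr <- make_trial_waveform("rate", 135, gap_ms = 0, reference = ref)
  cmp <- rate_tr$displacement_um[20001:40000]
  expect_equal(count_pulse_runs(new_wf(cmp)), 67) # floor(135 * 0.5)
  rp <- reconstruct_pulses(new_wf(cmp))
  expect_true(all(abs(rp$width_ms - 1000 / 170) <= 1000 / 40000))
})
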