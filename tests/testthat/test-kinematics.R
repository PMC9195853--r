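test_that("finite-difference kinematics match analytic derivatives", {
  fs <- 40000
  # degenerate inputs
  flat <- new_wf(rep(3, 100))
  expect_true(all(wf_velocity(flat)$value == 0))
  expect_error(wf_velocity(new_wf(c(1, 2))), "3 samples")

  ramp <- new_wf(seq(0, 99) * 2) # slope 2 um/sample = 2*fs um/s
  expect_equal(wf_velocity(ramp)$value, rep(2 * fs, 100), tolerance = 1e-9)
  acc <- wf_acceleration(ramp)$value
  # zero up to rounding noise amplified by 1/h (pulse accelerations are ~1e7)
  expect_true(all(abs(acc[3:98]) < 1e-3))

  # pulse extrema vs closed forms
  p <- make_pulse(pulse_spec(170, 40), fs)
  expect_equal(max(abs(wf_velocity(p)$value)), 2 * pi * 170 * 40,
               tolerance = 0.005)
  expect_equal(max(abs(wf_acceleration(p)$value)), (2 * pi * 170)^2 * 40,
               tolerance = 0.01)
  expect_true(all(wf_acceleration(new_wf(rep(0, 50)))$value == 0))
})

test_that("train intensities match closed-form oracles", {
  tr <- make_train(train_spec()) # 45 pulses, A = 40, D = 0.5 s
  expect_equal(
    intensity(tr, "mean_abs_v"),
    intensity_closed_form("mean_abs_v", 170, 40, 90, 0.5), # 14400 um/s
    tolerance = 0.005
  )
  expect_equal(
    intensity(tr, "mean_sq_v"),
    intensity_closed_form("mean_sq_v", 170, 40, 90, 0.5),
    tolerance = 0.01
  )
  expect_error(intensity(tr, "mean_cubed_jerk"), "unknown")
})

test_that("mean speed is invariant to waveform frequency at fixed rate", {
  v170 <- intensity(make_train(comparison_spec("shape", 170)), "mean_abs_v")
  v240 <- intensity(make_train(comparison_spec("shape", 240)), "mean_abs_v")
  expect_lt(abs(v170 - v240) / v170, 0.005)
})

test_that("iso-feature deviation separates shape and rate families", {
  shape_fam <- lapply(c(170, change_levels("shape")),
                      function(f) comparison_spec("shape", f))
  rate_fam <- lapply(c(90, change_levels("rate")),
                     function(r) comparison_spec("rate", r))
  expect_lt(iso_feature_deviation(shape_fam, "mean_abs_v"), 0.005)
  expect_gt(iso_feature_deviation(rate_fam, "mean_abs_v"), 0.1)
  expect_identical(iso_feature_deviation(shape_fam[1], "mean_abs_v"), 0)
})

test_that("intensities rise with amplitude, and with frequency except mean speed", {
  tags <- intensity_formulations()$tag
  prof <- function(f, a) {
    w <- make_train(train_spec(pulse = pulse_spec(f, a)))
    vapply(tags, function(tg) intensity(w, tg), numeric(1))
  }
  p40 <- prof(170, 40)
  p50 <- prof(170, 50)
  p60 <- prof(170, 60)
  expect_true(all(p50 > p40) && all(p60 > p50))

  f170 <- prof(170, 40)
  f205 <- prof(205, 40)
  f240 <- prof(240, 40)
  rising <- setdiff(tags, "mean_abs_v")
  expect_true(all(f205[rising] > f170[rising]))
  expect_true(all(f240[rising] > f205[rising]))
  expect_lt(abs(f240["mean_abs_v"] - f170["mean_abs_v"]) / f170["mean_abs_v"],
            0.005)
})

test_that("sampled intensities converge to closed forms as fs grows", {
  err <- vapply(c(40000, 80000, 160000), function(fs) {
    tr <- make_train(train_spec(sample_rate_hz = fs))
    abs(intensity(tr, "mean_sq_v") -
          intensity_closed_form("mean_sq_v", 170, 40, 90, 0.5))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("summed intensity equals mean times sample count", {
  tr <- make_train(train_spec())
  expect_equal(
    intensity(tr, "mean_abs_a", statistic = "sum"),
    intensity(tr, "mean_abs_a") * nrow(tr),
    tolerance = 1e-12
  )
})

test_that("intensity tables cover levels x formulations", {
  tab <- intensity_table("rate", levels = c(90, 110, 135))
  expect_equal(nrow(tab), 18)
  mav <- tab[tab$formulation == "mean_abs_v", ]
  # mean speed is linear in pulse rate: 4 A n / D
  expect_equal(mav$value, 4 * 40 * floor(mav$level * 0.5) / 0.5,
               tolerance = 0.005)
})
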