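test_that("decision variables map levels onto coding axes", {
  expect_equal(decision_variable(240, "shape", "pulse_width_ms"), 1000 / 240)
  expect_equal(round(decision_variable(240, "shape", "pulse_width_ms"), 3),
               4.167)
  expect_equal(round(decision_variable(170, "shape", "pulse_width_ms"), 3),
               5.882)
  expect_equal(decision_variable(c(95, 135), "rate", "pulse_rate_hz"),
               c(95, 135))
  # axes constant across the other condition's levels
  expect_equal(decision_variable(c(95, 135), "rate", "pulse_width_ms"),
               rep(1000 / 170, 2))
  expect_equal(decision_variable(c(175, 240), "shape", "pulse_rate_hz"),
               rep(90, 2))
  # mean speed is (near) constant across shape levels
  ref_v <- decision_variable(170, "shape", "intensity:mean_abs_v")
  lv_v <- decision_variable(change_levels("shape"), "shape",
                            "intensity:mean_abs_v")
  expect_true(all(abs(lv_v - ref_v) / ref_v < 0.005))
  expect_error(observer_spec("intensity:bogus", psychometric_params(1, 1)),
               "unknown coding axis")
})

test_that("a step observer responds deterministically by level", {
  obs <- observer_spec(
    "pulse_width_ms",
    psychometric_params(m = 0.9, w = 1e-6, gamma = 0, delta = 0)
  )
  sched <- build_schedule("shape", seed = 1)
  resp <- simulate_session(obs, sched, seed = 1)
  dv <- abs(1000 / resp$level - 1000 / 170)
  expect_identical(resp$response_yes, dv > 0.9)
})

test_that("an insensitive observer responds at its false-alarm rate", {
  obs <- observer_spec(
    "pulse_width_ms",
    psychometric_params(m = 50, w = 1, gamma = 0.1, delta = 0)
  )
  sched <- build_schedule("shape", seed = 2)
  resp <- simulate_session(obs, sched, seed = 3)
  noc <- resp$response_yes[!resp$is_change]
  expect_equal(length(noc), 420)
  # binomial 99.9% band around gamma = 0.1 at n = 420
  band <- 3.3 * sqrt(0.1 * 0.9 / 420)
  expect_lt(abs(mean(noc) - 0.1), band)
})

test_that("sessions are seed-deterministic", {
  obs <- width_observer()
  sched <- build_schedule("shape", seed = 4)
  expect_identical(simulate_session(obs, sched, seed = 5),
                   simulate_session(obs, sched, seed = 5))
  expect_false(identical(simulate_session(obs, sched, seed = 5)$response_yes,
                         simulate_session(obs, sched, seed = 6)$response_yes))
})

test_that("yes-rates converge to the generating curve with replication", {
  obs <- width_observer()
  p_true <- function(lv) {
    predict_psychometric(obs$params, abs(1000 / lv - 1000 / 170))
  }
  dev_at <- function(reps, seed) {
    sched <- build_schedule("shape", seed = seed, reps_per_level = reps)
    resp <- simulate_session(obs, sched, seed = seed + 1)
    chg <- resp[resp$is_change, ]
    agg <- tapply(chg$response_yes, chg$level, mean)
    max(abs(agg - p_true(as.numeric(names(agg)))))
  }
  expect_lt(dev_at(3000, 10), dev_at(30, 10))
})

test_that("full-lapse mode flips responses symmetrically", {
  obs <- observer_spec(
    "pulse_width_ms",
    psychometric_params(m = 50, w = 1, gamma = 0.1, delta = 0.3),
    full_lapse = TRUE
  )
  sched <- build_schedule("shape", seed = 7, reps_per_level = 90)
  resp <- simulate_session(obs, sched, seed = 8)
  noc <- mean(resp$response_yes[!resp$is_change])
  target <- 0.1 * (1 - 0.3) + 0.9 * 0.3 # gamma(1-delta) + (1-gamma)delta
  expect_lt(abs(noc - target), 3.3 * sqrt(target * (1 - target) / 1260))
})

test_that("gap sessions inflate the observer's width", {
  obs <- width_observer(inflation = 3)
  # near the reference the inflated curve is shallower -> more misses at
  # intermediate deltas
  sg <- build_schedule("shape", gap_ms = 0, seed = 1, reps_per_level = 300)
  gg <- build_schedule("shape", gap_ms = 1000, seed = 1, reps_per_level = 300)
  r_ng <- simulate_session(obs, sg, seed = 2)
  r_g <- simulate_session(obs, gg, seed = 2)
  top <- function(r) mean(r$response_yes[r$is_change & r$level == 240])
  expect_gt(top(r_ng), top(r_g))
})

test_that("cohorts run four counterbalanced sessions per participant", {
  resp <- simulate_cohort(2, population_spec(), seed = 11, reps_per_level = 3)
  tot <- dplyr::count(resp, .data$participant_id, .data$condition, .data$gap_ms)
  expect_equal(nrow(tot), 8)

  full <- simulate_cohort(1, population_spec(), seed = 12)
  expect_equal(nrow(full), 840 + 840 + 540 + 540)
  sizes <- sort(dplyr::count(full, .data$condition, .data$gap_ms)$n)
  expect_equal(sizes, c(540, 540, 840, 840))

  # session order is counterbalanced: first sessions differ across the cohort
  many <- simulate_cohort(6, population_spec(), seed = 13, reps_per_level = 3)
  first <- many |>
    dplyr::filter(.data$session == 1) |>
    dplyr::distinct(.data$participant_id, .data$condition, .data$gap_ms)
  expect_gt(nrow(dplyr::distinct(first, .data$condition, .data$gap_ms)), 1)

  expect_identical(
    simulate_cohort(2, population_spec(), seed = 14, reps_per_level = 3),
    simulate_cohort(2, population_spec(), seed = 14, reps_per_level = 3)
  )
})

test_that("response tables round-trip through CSV", {
  resp <- simulate_cohort(1, population_spec(), seed = 15, reps_per_level = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, path)
  expect_equal(as.data.frame(read_responses(path)), as.data.frame(resp))
})
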