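#' Reference values of the change-detection design
#'
#' The reference stimulus in every session is a 500 ms train at 90 Hz pulse
#' rate built from 170 Hz / 40 um pulses. Shape-change sessions vary the
#' comparison waveform frequency over 175-240 Hz in 5 Hz steps (14 levels);
#' rate-change sessions vary the comparison pulse rate over 95-135 Hz in 5 Hz
#' steps (9 levels). The reference value itself is not a change level.
#'
#' @param condition `"shape"` or `"rate"`.
#' @return `reference_level()`: the reference value (Hz);
#'   `change_levels()`: the vector of comparison levels (Hz).
#' @export
reference_level <- function(condition) {
  condition <- match.arg(condition, c("shape", "rate"))
  c(shape = 170, rate = 90)[[condition]]
}

#' @rdname reference_level
#' @export
change_levels <- function(condition) {
  condition <- match.arg(condition, c("shape", "rate"))
  if (condition == "shape") seq(175, 240, by = 5) else seq(95, 135, by = 5)
}

#' Build a session schedule
#'
#' Generates the ordered trial list of one testing session using the method
#' of constant stimuli: each change level is presented `reps_per_level`
#' times, and an equal number of no-change trials (comparison identical to
#' the reference) is added so that exactly 50% of trials are no-change. The
#' trials are spread over `blocks` blocks with equal per-level counts in each
#' block, and the order within each block is a seeded uniform permutation.
#' With the defaults this yields 840 trials (3 x 280) for shape sessions and
#' 540 trials (3 x 180) for rate sessions.
#'
#' @param condition `"shape"` or `"rate"`.
#' @param gap_ms Gap between reference and comparison (0 or 1000 ms).
#' @param seed Integer seed for the trial-order permutation.
#' @param reps_per_level Presentations of each change level; must be
#'   divisible by `blocks`. Default 30.
#' @param blocks Number of testing blocks. Default 3.
#' @param practice If `TRUE`, prepend 20 practice trials (10 change at
#'   random levels, 10 no-change) in block 0, flagged by `practice_flag`.
#'   Practice trials are excluded from analysis downstream.
#' @return A tibble with columns `trial_index`, `block`, `condition`,
#'   `is_change`, `level`, `gap_ms`, `practice_flag`.
#' @export
#' @examples
#' sched <- build_schedule("rate", gap_ms = 1000, seed = 7)
#' nrow(sched)           # 540
#' table(sched$block)    # 180 per block
build_schedule <- function(condition, gap_ms = 0, seed = 1,
                           reps_per_level = 30, blocks = 3,
                           practice = FALSE) {
  condition <- match.arg(condition, c("shape", "rate"))
  stopifnot(
    gap_ms >= 0, reps_per_level >= 1, blocks >= 1,
    reps_per_level %% blocks == 0
  )
  levels <- change_levels(condition)
  ref <- reference_level(condition)
  per_block_reps <- reps_per_level / blocks
  n_change_block <- length(levels) * per_block_reps
  withr::with_seed(seed, {
    block_trials <- purrr::map(seq_len(blocks), function(b) {
      lv <- c(rep(levels, each = per_block_reps), rep(ref, n_change_block))
      chg <- c(rep(TRUE, n_change_block), rep(FALSE, n_change_block))
      ord <- sample.int(length(lv))
      tibble::tibble(
        block = b, is_change = chg[ord], level = lv[ord],
        practice_flag = FALSE
      )
    })
    sched <- dplyr::bind_rows(block_trials)
    if (practice) {
      lv <- c(sample(levels, 10, replace = TRUE), rep(ref, 10))
      chg <- c(rep(TRUE, 10), rep(FALSE, 10))
      ord <- sample.int(20)
      sched <- dplyr::bind_rows(
        tibble::tibble(
          block = 0, is_change = chg[ord], level = lv[ord],
          practice_flag = TRUE
        ),
        sched
      )
    }
  })
  sched |>
    dplyr::mutate(
      trial_index = dplyr::row_number(),
      condition = condition,
      gap_ms = gap_ms
    ) |>
    dplyr::select(
      "trial_index", "block", "condition", "is_change", "level",
      "gap_ms", "practice_flag"
    )
}

#' Read or write a schedule CSV
#'
#' @param schedule A schedule tibble from [build_schedule()].
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      trial_index = readr::col_integer(),
      block = readr::col_integer(),
      condition = readr::col_character(),
      is_change = readr::col_logical(),
      level = readr::col_double(),
      gap_ms = readr::col_double(),
      practice_flag = readr::col_logical()
    )
  )
}
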