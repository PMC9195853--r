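#' Aggregate a response table into per-session binomial data
#'
#' For each (participant, condition, gap) cell, counts "yes" responses per
#' change level and computes the empirical false-alarm rate (proportion "yes"
#' on no-change trials).
#'
#' @param responses A response tibble (see [simulate_session()]).
#' @return A tibble with one row per participant x condition x gap:
#'   `participant_id`, `condition`, `gap_ms`, `data` (list column of
#'   level/n/k tibbles over change levels), `fa_rate`, `n_nochange`,
#'   `k_nochange`.
#' @export
aggregate_responses <- function(responses) {
  stopifnot(all(c(
    "participant_id", "condition", "gap_ms", "level", "is_change",
    "response_yes"
  ) %in% names(responses)))
  responses |>
    dplyr::group_by(.data$participant_id, .data$condition, .data$gap_ms) |>
    dplyr::group_modify(function(df, key) {
      chg <- df |>
        dplyr::filter(.data$is_change) |>
        dplyr::group_by(.data$level) |>
        dplyr::summarise(
          n = dplyr::n(), k = sum(.data$response_yes), .groups = "drop"
        ) |>
        dplyr::arrange(.data$level)
      noc <- dplyr::filter(df, !.data$is_change)
      tibble::tibble(
        data = list(chg),
        fa_rate = if (nrow(noc) > 0) mean(noc$response_yes) else NA_real_,
        n_nochange = nrow(noc),
        k_nochange = sum(noc$response_yes)
      )
    }) |>
    dplyr::ungroup()
}

#' Fit every participant x session of a response table
#'
#' Aggregates the responses and fits the psychometric mixture model to each
#' cell. No-change trials inform the false-alarm rate in one of three modes:
#' `"reference_point"` (default) adds them as a data point at the reference
#' level with `gamma` left free; `"fixed"` fixes `gamma` at the empirical
#' false-alarm rate; `"ignore"` uses change trials only. Valid fits get a
#' corrected threshold on the native axis (waveform frequency in Hz for
#' shape, pulse rate in Hz for rate) and its percent-change conversion.
#'
#' @param responses A response tibble.
#' @param gamma_mode How no-change trials enter the fit (see above).
#' @param sigmoid,n_starts,seed Passed to [fit_psychometric()].
#' @param keep_fits If `TRUE`, attach the `psyfit` objects as a list column.
#' @return A threshold-record tibble: `participant_id`, `condition`,
#'   `gap_ms`, `valid`, `invalid_reason`, `threshold_native`,
#'   `threshold_pct_change`, `fa_rate`, `m`, `w`, `gamma`, `delta`,
#'   `neg_log_lik` (plus `fit` if `keep_fits`).
#' @export
#' @examples
#' resp <- simulate_cohort(2, population_spec(), seed = 3, reps_per_level = 5)
#' fit_cohort(resp, n_starts = 4)
fit_cohort <- function(responses,
                       gamma_mode = c("reference_point", "fixed", "ignore"),
                       sigmoid = c("cumulative_gaussian", "logistic"),
                       n_starts = 16, seed = 1, keep_fits = FALSE) {
  gamma_mode <- match.arg(gamma_mode)
  sigmoid <- match.arg(sigmoid)
  agg <- aggregate_responses(responses)
  fits <- purrr::pmap(
    list(agg$data, agg$condition, agg$fa_rate, agg$n_nochange, agg$k_nochange),
    function(data, condition, fa_rate, n_nochange, k_nochange) {
      ref <- reference_level(condition)
      fix_gamma <- NULL
      if (gamma_mode == "reference_point" && n_nochange > 0) {
        data <- dplyr::bind_rows(
          tibble::tibble(level = ref, n = n_nochange, k = k_nochange),
          data
        ) |> dplyr::arrange(.data$level)
      } else if (gamma_mode == "fixed" && n_nochange > 0) {
        fix_gamma <- min(fa_rate, 0.499)
      }
      fit_psychometric(
        data, sigmoid = sigmoid, n_starts = n_starts, seed = seed,
        fix_gamma = fix_gamma
      )
    }
  )
  out <- agg |>
    dplyr::mutate(
      valid = purrr::map_lgl(fits, "valid"),
      invalid_reason = purrr::map_chr(fits, "invalid_reason"),
      threshold_native = purrr::map_dbl(fits, "threshold_corrected"),
      m = purrr::map_dbl(fits, ~ if (is.null(.x$params)) NA_real_ else .x$params$m),
      w = purrr::map_dbl(fits, ~ if (is.null(.x$params)) NA_real_ else .x$params$w),
      gamma = purrr::map_dbl(fits, ~ if (is.null(.x$params)) NA_real_ else .x$params$gamma),
      delta = purrr::map_dbl(fits, ~ if (is.null(.x$params)) NA_real_ else .x$params$delta),
      neg_log_lik = purrr::map_dbl(fits, "neg_log_lik"),
      threshold_pct_change = percent_change(.data$threshold_native, .data$condition)
    ) |>
    dplyr::select(-"data")
  if (keep_fits) out$fit <- fits
  out
}

#' Convert a native threshold to percent change
#'
#' Thresholds are expressed as the percentage change of the manipulated
#' quantity relative to the reference stimulus. Rate sessions manipulate the
#' pulse rate: `100 * (rate - 90) / 90`. Shape sessions manipulate the pulse
#' width (which shrinks as the waveform frequency grows):
#' `100 * (width_ref - width) / width_ref = 100 * (1 - 170 / f)`.
#'
#' @param threshold_native Threshold(s) on the native axis (Hz).
#' @param condition `"shape"` or `"rate"` (vectorised, recycled).
#' @return Percent change value(s).
#' @export
#' @examples
#' percent_change(135, "rate")   # 50
#' percent_change(240, "shape")  # 29.17
percent_change <- function(threshold_native, condition) {
  stopifnot(all(condition %in% c("shape", "rate")))
  ref <- c(shape = 170, rate = 90)[condition]
  ifelse(
    condition == "shape",
    100 * (1 - ref / threshold_native),
    100 * (threshold_native - ref) / ref
  )
}

#' Paired comparison of gap vs no-gap thresholds
#'
#' Restricted to participants with a valid fit in both the gap and the no-gap
#' session of a condition: paired t-test on the native thresholds, the
#' probability-of-superiority effect size (proportion of pairs where the gap
#' threshold exceeds the no-gap threshold, ties counted one half — reported
#' as `auc`), and the Pearson correlation between the paired thresholds.
#'
#' @param records A threshold-record tibble from [fit_cohort()].
#' @param condition Condition to compare (`"shape"` or `"rate"`); if `NULL`,
#'   each condition present is compared.
#' @return A tibble with one row per condition: `condition`, `n_pairs`,
#'   `dof`, `t_statistic`, `p_value`, `auc`, `pearson_r`,
#'   `mean_diff` (gap minus no-gap).
#' @export
compare_gap_nogap <- function(records, condition = NULL) {
  stopifnot(all(c(
    "participant_id", "condition", "gap_ms", "valid", "threshold_native"
  ) %in% names(records)))
  conds <- if (is.null(condition)) unique(records$condition) else condition
  purrr::map_dfr(conds, function(cnd) {
    wide <- records |>
      dplyr::filter(.data$condition == cnd, .data$valid) |>
      dplyr::mutate(gap = ifelse(.data$gap_ms > 0, "gap", "nogap")) |>
      dplyr::select("participant_id", "gap", "threshold_native") |>
      tidyr::pivot_wider(names_from = "gap", values_from = "threshold_native")
    for (colnm in c("gap", "nogap")) {
      if (!colnm %in% names(wide)) wide[[colnm]] <- NA_real_
    }
    wide <- wide[complete.cases(wide[, c("gap", "nogap")]), ]
    n_pairs <- nrow(wide)
    if (n_pairs < 2) {
      stop(
        "need at least 2 participants valid in both gap and no-gap (",
        cnd, " has ", n_pairs, ")", call. = FALSE
      )
    }
    d <- wide$gap - wide$nogap
    if (stats::sd(d) == 0) {
      # degenerate paired data: zero differences give t = 0, p = 1
      tt <- list(
        statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
        parameter = c(df = n_pairs - 1),
        p.value = if (mean(d) == 0) 1 else 0
      )
    } else {
      tt <- t.test(wide$gap, wide$nogap, paired = TRUE)
    }
    r <- if (stats::sd(wide$gap) > 0 && stats::sd(wide$nogap) > 0) {
      cor(wide$gap, wide$nogap)
    } else {
      NA_real_
    }
    tibble::tibble(
      condition = cnd,
      n_pairs = n_pairs,
      dof = as.integer(unname(tt$parameter)),
      t_statistic = unname(tt$statistic),
      p_value = tt$p.value,
      auc = mean(d > 0) + 0.5 * mean(d == 0),
      pearson_r = r,
      mean_diff = mean(d)
    )
  })
}

#' Validity census of fitted sessions
#'
#' Counts valid psychometric fits per condition x gap cell, and reports how
#' many participants were invalid in the no-gap shape session (the exclusion
#' bookkeeping applied before any further analysis).
#'
#' @param records A threshold-record tibble from [fit_cohort()].
#' @return A list with `census` (tibble: `condition`, `gap_ms`, `n_valid`,
#'   `n_total`) and `excluded_participants` (ids invalid on no-gap shape).
#' @export
validity_census <- function(records) {
  census <- if (nrow(records) == 0) {
    tibble::tibble(
      condition = character(), gap_ms = numeric(),
      n_valid = integer(), n_total = integer()
    )
  } else {
    records |>
      dplyr::group_by(.data$condition, .data$gap_ms) |>
      dplyr::summarise(
        n_valid = sum(.data$valid), n_total = dplyr::n(), .groups = "drop"
      )
  }
  excluded <- records |>
    dplyr::filter(.data$condition == "shape", .data$gap_ms == 0, !.data$valid) |>
    dplyr::pull(.data$participant_id)
  list(census = census, excluded_participants = excluded)
}

#' Rescale responses to an intensity axis and refit
#'
#' Maps each change level (and the reference) of a condition to the
#' corresponding kinematic intensity of the synthesised comparison train,
#' then refits the psychometric model (logistic sigmoid) on the shared
#' intensity axis. If the formulation is constant across the condition's
#' levels — mean speed under shape changes, by stimulus design — the axis is
#' degenerate and the fit is skipped with an explicit flag.
#'
#' @param responses A response tibble (one or more participants).
#' @param formulation An intensity tag (see [intensity_formulations()]).
#' @param condition `"shape"` or `"rate"`.
#' @param gap Select gap (`TRUE`) or no-gap (`FALSE`) sessions. Default
#'   `FALSE`.
#' @param mode `"pooled"` pools trials over participants before fitting
#'   (default); `"individual"` fits each participant and averages the
#'   threshold estimates.
#' @param degenerate_tol Relative axis span below which the axis is declared
#'   degenerate. Default 0.005 (the iso-feature tolerance).
#' @param n_starts,seed Passed to [fit_psychometric()].
#' @param statistic Intensity statistic, `"mean"` or `"sum"` (axis scaling
#'   only; does not change the fit up to the affine invariance of the model).
#' @param reference Reference [train_spec()].
#' @return A one-row tibble: `condition`, `gap_ms`, `formulation`,
#'   `degenerate`, `axis_min`, `axis_max`, `threshold_intensity`, `m`, `w`,
#'   `gamma`, `delta`, `valid`, plus a `fit` list column (`NULL` when
#'   degenerate).
#' @export
rescale_to_intensity <- function(responses, formulation, condition,
                                 gap = FALSE,
                                 mode = c("pooled", "individual"),
                                 degenerate_tol = 0.005,
                                 n_starts = 16, seed = 1,
                                 statistic = c("mean", "sum"),
                                 reference = train_spec()) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  stopifnot(condition %in% c("shape", "rate"))
  gap_sel <- if (gap) quote(gap_ms > 0) else quote(gap_ms == 0)
  resp <- responses |>
    dplyr::filter(.data$condition == !!condition, !!gap_sel)
  if (nrow(resp) == 0) stop("no responses for the requested cell", call. = FALSE)

  lv <- sort(unique(resp$level[resp$is_change]))
  ref <- reference_level(condition)
  axis_levels <- c(ref, lv)
  axis_vals <- purrr::map_dbl(axis_levels, function(x) {
    w <- make_train(comparison_spec(condition, x, reference))
    intensity(w, formulation, statistic)
  })
  names(axis_vals) <- as.character(axis_levels)
  span_rel <- diff(range(axis_vals)) / mean(axis_vals)

  base <- tibble::tibble(
    condition = condition, gap_ms = if (gap) 1000 else 0,
    formulation = formulation,
    degenerate = span_rel < degenerate_tol,
    axis_min = min(axis_vals), axis_max = max(axis_vals)
  )
  if (base$degenerate) {
    return(dplyr::mutate(
      base,
      threshold_intensity = NA_real_, m = NA_real_, w = NA_real_,
      gamma = NA_real_, delta = NA_real_, valid = FALSE,
      fit = list(NULL)
    ))
  }

  fit_one <- function(df) {
    counts <- df |>
      dplyr::mutate(axis = axis_vals[as.character(.data$level)]) |>
      dplyr::group_by(.data$axis) |>
      dplyr::summarise(
        n = dplyr::n(), k = sum(.data$response_yes), .groups = "drop"
      ) |>
      dplyr::arrange(.data$axis)
    fit_psychometric(
      binomial_data(counts$axis, counts$n, counts$k),
      sigmoid = "logistic", n_starts = n_starts, seed = seed
    )
  }

  if (mode == "pooled") {
    fit <- fit_one(resp)
    dplyr::mutate(
      base,
      threshold_intensity = fit$threshold_corrected,
      m = fit$params$m, w = fit$params$w,
      gamma = fit$params$gamma, delta = fit$params$delta,
      valid = fit$valid, fit = list(fit)
    )
  } else {
    fits <- resp |>
      dplyr::group_split(.data$participant_id) |>
      purrr::map(fit_one)
    ok <- purrr::map_lgl(fits, "valid")
    thr <- purrr::map_dbl(fits, "threshold_corrected")
    dplyr::mutate(
      base,
      threshold_intensity = if (any(ok)) mean(thr[ok]) else NA_real_,
      m = mean(purrr::map_dbl(fits[ok], ~ .x$params$m)),
      w = mean(purrr::map_dbl(fits[ok], ~ .x$params$w)),
      gamma = mean(purrr::map_dbl(fits[ok], ~ .x$params$gamma)),
      delta = mean(purrr::map_dbl(fits[ok], ~ .x$params$delta)),
      valid = any(ok), fit = list(fits)
    )
  }
}

#' Intensity-axis overlay table for all six formulations
#'
#' Runs [rescale_to_intensity()] for every formulation over both conditions
#' in one gap state, producing the overlay bookkeeping used to compare shape
#' and rate performance on shared intensity axes.
#'
#' @inheritParams rescale_to_intensity
#' @return A tibble with one row per formulation x condition (no `fit`
#'   column).
#' @export
intensity_overlays <- function(responses, gap = FALSE,
                               mode = c("pooled", "individual"),
                               n_starts = 16, seed = 1,
                               reference = train_spec()) {
  mode <- match.arg(mode)
  grid <- tidyr::expand_grid(
    formulation = intensity_formulations()$tag,
    condition = intersect(c("shape", "rate"), unique(responses$condition))
  )
  purrr::pmap_dfr(grid, function(formulation, condition) {
    rescale_to_intensity(
      responses, formulation, condition, gap = gap, mode = mode,
      n_starts = n_starts, seed = seed, reference = reference
    ) |> dplyr::select(-"fit")
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
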