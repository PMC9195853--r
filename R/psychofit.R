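#' Psychometric mixture-model parameters
#'
#' The detection model is the four-parameter mixture
#' `P(x; m, w, gamma, delta) = gamma + (1 - delta - gamma) * S(x; m, w)`,
#' where `S` is a sigmoid (cumulative Gaussian by default, optionally
#' logistic), `m` is the stimulus level at which `S(x) = 0.5` (the threshold
#' of the underlying sigmoid), `w` is the width — the interval over which `S`
#' rises from 0.05 to 0.95, `gamma` is the false-alarm rate (lower asymptote)
#' and `delta` the lapse rate (upper asymptote shortfall).
#'
#' For the cumulative Gaussian the width definition fixes the scale at
#' `sigma = w / (2 * qnorm(0.95))`; for the logistic, `scale = w / (2 * log(19))`.
#'
#' @param m Threshold of the sigmoid (stimulus-axis units).
#' @param w Positive width (same units).
#' @param gamma False-alarm rate in `[0, 0.5)`.
#' @param delta Lapse rate in `[0, 0.5)`.
#' @param sigmoid `"cumulative_gaussian"` or `"logistic"`.
#' @return An object of class `psychometric_params`.
#' @export
#' @examples
#' p <- psychometric_params(m = 205, w = 40, gamma = 0.1, delta = 0.02)
#' predict_psychometric(p, c(170, 205, 240))
psychometric_params <- function(m, w, gamma = 0, delta = 0,
                                sigmoid = c("cumulative_gaussian", "logistic")) {
  sigmoid <- match.arg(sigmoid)
  stopifnot(
    is.numeric(m), length(m) == 1,
    is.numeric(w), length(w) == 1, w > 0,
    is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma < 0.5,
    is.numeric(delta), length(delta) == 1, delta >= 0, delta < 0.5,
    gamma + delta < 1
  )
  structure(
    list(m = m, w = w, gamma = gamma, delta = delta, sigmoid = sigmoid),
    class = "psychometric_params"
  )
}

#' @export
print.psychometric_params <- function(x, ...) {
  cat(
    "Psychometric mixture parameters (", x$sigmoid, ")\n",
    "  m = ", format(x$m), ", w = ", format(x$w),
    ", gamma = ", format(x$gamma), ", delta = ", format(x$delta), "\n",
    sep = ""
  )
  invisible(x)
}

# Width-to-scale conversion constants: S spans 0.05..0.95 over w.
scale_from_width <- function(w, sigmoid) {
  switch(sigmoid,
    cumulative_gaussian = w / (2 * qnorm(0.95)),
    logistic = w / (2 * log(19)),
    stop("unknown sigmoid: ", sigmoid, call. = FALSE)
  )
}

sigmoid_value <- function(x, m, w, sigmoid) {
  s <- scale_from_width(w, sigmoid)
  switch(sigmoid,
    cumulative_gaussian = pnorm((x - m) / s),
    logistic = plogis((x - m) / s)
  )
}

#' Predicted probability of a "change" response
#'
#' Evaluates the mixture model `gamma + (1 - delta - gamma) * S(x; m, w)`.
#' Non-decreasing in `x`, bounded in `[gamma, 1 - delta]`.
#'
#' @param params A [psychometric_params()].
#' @param x Stimulus level(s).
#' @return Probabilities, same length as `x`.
#' @export
predict_psychometric <- function(params, x) {
  stopifnot(inherits(params, "psychometric_params"))
  params$gamma + (1 - params$delta - params$gamma) *
    sigmoid_value(x, params$m, params$w, params$sigmoid)
}

#' Binomial response data for one psychometric fit
#'
#' Validates a (level, n, k) table: strictly increasing levels, `0 <= k <= n`.
#'
#' @param level Stimulus levels (strictly increasing).
#' @param n Trials per level (positive integers).
#' @param k "Yes" (change reported) counts per level.
#' @return A tibble with columns `level`, `n`, `k`.
#' @export
binomial_data <- function(level, n, k) {
  stopifnot(
    length(level) == length(n), length(n) == length(k),
    all(diff(level) > 0),
    all(n >= 1), all(k >= 0), all(k <= n),
    all(n == round(n)), all(k == round(k))
  )
  tibble::tibble(level = as.numeric(level), n = as.integer(n), k = as.integer(k))
}

#' Negative log-likelihood of binomial response data
#'
#' `-sum(k * log(P) + (n - k) * log(1 - P))` with the predicted probabilities
#' clamped to `[1e-9, 1 - 1e-9]` so saturated predictions stay finite.
#'
#' @param params A [psychometric_params()].
#' @param data A tibble with columns `level`, `n`, `k` (see [binomial_data()]).
#' @return The negative log-likelihood (scalar).
#' @export
neg_log_likelihood <- function(params, data) {
  p <- predict_psychometric(params, data$level)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(data$k * log(p) + (data$n - data$k) * log(1 - p))
}

#' Default fit bounds
#'
#' Box constraints for the maximum-likelihood search: `m` within the tested
#' range extended by the width cap on both sides, `w` in (0, 2 x level span],
#' and `gamma`, `delta` in `[0, 0.1]` (a psignifit-like lapse cap) unless
#' overridden.
#'
#' @param level Stimulus levels of the data.
#' @param gamma_max,delta_max Upper bounds for the asymptote parameters.
#' @return A list with `lower` and `upper` named numeric vectors over
#'   `(m, w, gamma, delta)`.
#' @export
fit_bounds <- function(level, gamma_max = 0.1, delta_max = 0.1) {
  span <- diff(range(level))
  stopifnot(span > 0)
  w_max <- 2 * span
  list(
    lower = c(m = min(level) - w_max, w = span * 1e-3, gamma = 0, delta = 0),
    upper = c(m = max(level) + w_max, w = w_max, gamma = gamma_max, delta = delta_max)
  )
}

#' Fit the psychometric mixture model by maximum likelihood
#'
#' Bounded multistart maximum-likelihood estimation of `(m, w, gamma, delta)`.
#' Starting points are a seeded Latin-hypercube sample over the box bounds
#' (plus one moment-based start); each start is refined with `L-BFGS-B`. The
#' best converged start by negative log-likelihood (ties broken by smaller
#' `w`) is retained, then the fit is classified as valid or invalid and the
#' false-alarm-corrected threshold extracted (see [classify_validity()]).
#'
#' @param data A tibble with columns `level`, `n`, `k`, or a data frame of raw
#'   trials with columns `level` and `response_yes` (aggregated internally).
#' @param sigmoid `"cumulative_gaussian"` (default) or `"logistic"`.
#' @param n_starts Number of multistart points. Default 16.
#' @param seed Seed for the start sample.
#' @param bounds Optional list with `lower`/`upper` as from [fit_bounds()].
#' @param fix_gamma Optional value to fix the false-alarm rate at (e.g. the
#'   empirical rate from no-change trials) instead of estimating it.
#' @param level_range Range over which the corrected threshold must lie for
#'   the fit to be valid; defaults to the range of `data$level`.
#' @return An object of class `psyfit`: a list with elements `params`
#'   ([psychometric_params()]), `neg_log_lik`, `valid`, `invalid_reason`
#'   (`NA` or one of `"did_not_reach_half"`, `"threshold_on_limit"`,
#'   `"fit_failed"`), `threshold_corrected`, `data`, `level_range`,
#'   `n_starts`, `seed`.
#' @export
#' @examples
#' truth <- psychometric_params(m = 205, w = 40, gamma = 0.1, delta = 0.02)
#' lv <- seq(175, 240, 5)
#' set.seed(1)
#' k <- rbinom(length(lv), 30, predict_psychometric(truth, lv))
#' fit <- fit_psychometric(binomial_data(lv, rep(30, length(lv)), k))
#' glance(fit)
fit_psychometric <- function(data,
                             sigmoid = c("cumulative_gaussian", "logistic"),
                             n_starts = 16, seed = 1, bounds = NULL,
                             fix_gamma = NULL, level_range = NULL) {
  sigmoid <- match.arg(sigmoid)
  if ("response_yes" %in% names(data)) {
    data <- data |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(
        n = dplyr::n(), k = sum(.data$response_yes), .groups = "drop"
      ) |>
      dplyr::arrange(.data$level)
  }
  data <- binomial_data(data$level, data$n, data$k)
  if (nrow(data) < 4) {
    stop("need at least 4 stimulus levels to fit", call. = FALSE)
  }
  if (is.null(bounds)) bounds <- fit_bounds(data$level)
  if (is.null(level_range)) level_range <- range(data$level)
  lower <- bounds$lower
  upper <- bounds$upper
  # with gamma fixed, optimize over the remaining three parameters
  free <- if (is.null(fix_gamma)) 1:4 else c(1, 2, 4)
  if (!is.null(fix_gamma)) stopifnot(fix_gamma >= 0, fix_gamma < 0.5)

  nll_full <- function(par) {
    g <- min(max(par[3], 0), 0.499)
    d <- min(max(par[4], 0), 0.499)
    p <- g + (1 - d - g) * sigmoid_value(data$level, par[1], max(par[2], 1e-12), sigmoid)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    -sum(data$k * log(p) + (data$n - data$k) * log(1 - p))
  }
  expand_par <- function(p) {
    par <- numeric(4)
    par[free] <- p
    if (!is.null(fix_gamma)) par[3] <- fix_gamma
    par
  }
  nll_vec <- function(p) nll_full(expand_par(p))

  starts <- withr::with_seed(seed, {
    u <- lhs::randomLHS(n_starts, 4)
    sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  })
  # moment-based start: midpoint of the empirical rise
  phat <- data$k / data$n
  m0 <- data$level[which.min(abs(phat - 0.5))]
  starts <- rbind(starts, c(m0, diff(range(data$level)) / 2,
                            min(max(phat[1], 0.01), upper["gamma"]),
                            min(0.02, max(upper["delta"], 0))))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(
        par = pmin(pmax(starts[i, ], lower), upper)[free],
        fn = nll_vec, method = "L-BFGS-B",
        lower = lower[free], upper = upper[free],
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) ||
        res$value < best$value - 1e-9 ||
        (abs(res$value - best$value) <= 1e-9 && res$par[2] < best$par[2])) {
      best <- res
    }
  }
  if (!is.null(best)) best$par <- expand_par(best$par)

  if (is.null(best)) {
    out <- structure(
      list(
        params = NULL, neg_log_lik = NA_real_, valid = FALSE,
        invalid_reason = "fit_failed", threshold_corrected = NA_real_,
        data = data, level_range = level_range, sigmoid = sigmoid,
        n_starts = n_starts, seed = seed
      ),
      class = "psyfit"
    )
    return(out)
  }

  params <- psychometric_params(
    m = best$par[1], w = max(best$par[2], 1e-12),
    gamma = min(max(best$par[3], 0), 0.499),
    delta = min(max(best$par[4], 0), 0.499),
    sigmoid = sigmoid
  )
  fit <- structure(
    list(
      params = params, neg_log_lik = best$value, valid = NA,
      invalid_reason = NA_character_, threshold_corrected = NA_real_,
      data = data, level_range = level_range, sigmoid = sigmoid,
      n_starts = n_starts, seed = seed
    ),
    class = "psyfit"
  )
  classify_validity(fit)
}

#' False-alarm correction
#'
#' Standard high-threshold correction `(p - gamma) / (1 - gamma)`, clipped to
#' `[0, 1]`: rescales response probabilities so that guessing at the
#' false-alarm rate maps to 0.
#'
#' @param p Probabilities.
#' @param gamma False-alarm rate in `[0, 1)`.
#' @return Corrected probabilities.
#' @export
false_alarm_correct <- function(p, gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0)
  if (gamma >= 1) stop("gamma must be < 1", call. = FALSE)
  pmin(pmax((p - gamma) / (1 - gamma), 0), 1)
}

corrected_prob <- function(params, x) {
  false_alarm_correct(predict_psychometric(params, x), params$gamma)
}

#' Corrected threshold of a fitted psychometric function
#'
#' Solves `false_alarm_correct(P(x), gamma) = 0.5` for `x` by monotone
#' root-finding within `level_range`. With `delta = 0` the corrected curve
#' crosses 0.5 exactly at `m`; a positive lapse rate shifts the crossing
#' above `m`.
#'
#' @param params A [psychometric_params()] (or a `psyfit`, whose params are
#'   used).
#' @param level_range Length-2 numeric range to search.
#' @return The threshold, or `NA` if the corrected curve does not cross 0.5
#'   inside the range.
#' @export
threshold_from_params <- function(params, level_range) {
  if (inherits(params, "psyfit")) params <- params$params
  stopifnot(inherits(params, "psychometric_params"), length(level_range) == 2)
  f <- function(x) corrected_prob(params, x) - 0.5
  lo <- f(level_range[1])
  hi <- f(level_range[2])
  if (hi < 0 || lo > 0) return(NA_real_)
  if (lo == 0) return(level_range[1])
  if (hi == 0) return(level_range[2])
  uniroot(f, interval = level_range, tol = 1e-10)$root
}

#' Classify the validity of a psychometric fit
#'
#' Applies the exclusion rules used for change-detection performance: a fit is
#' invalid if (1) the false-alarm-corrected curve does not reach 0.5 within
#' the tested stimulus range (`did_not_reach_half`), or (2) the corrected
#' threshold lies on the limit of the stimulus range (`threshold_on_limit`,
#' judged with a relative tolerance of 1e-3 of the range span; a curve whose
#' corrected maximum grazes 0.5 from below — within 0.01 — is classified as a
#' boundary threshold rather than a flat curve). Valid fits get their
#' corrected threshold stored.
#'
#' @param fit A `psyfit` object.
#' @return The `psyfit` with `valid`, `invalid_reason` and
#'   `threshold_corrected` filled in.
#' @export
classify_validity <- function(fit) {
  stopifnot(inherits(fit, "psyfit"))
  if (is.null(fit$params)) {
    fit$valid <- FALSE
    fit$invalid_reason <- "fit_failed"
    return(fit)
  }
  rng <- fit$level_range
  span <- diff(rng)
  tol <- 1e-3 * span
  p_hi <- corrected_prob(fit$params, rng[2])
  p_lo <- corrected_prob(fit$params, rng[1])
  if (p_hi < 0.5) {
    fit$valid <- FALSE
    # a curve grazing 0.5 at the upper limit is a boundary threshold, not a
    # flat curve; distinguish the two with a small probability band
    fit$invalid_reason <- if (p_hi >= 0.49) "threshold_on_limit" else "did_not_reach_half"
    return(fit)
  }
  if (p_lo >= 0.5) {
    # crossed at or below the lowest tested level
    fit$valid <- FALSE
    fit$invalid_reason <- "threshold_on_limit"
    return(fit)
  }
  thr <- threshold_from_params(fit$params, rng)
  if (is.na(thr) || thr <= rng[1] + tol || thr >= rng[2] - tol) {
    fit$valid <- FALSE
    fit$invalid_reason <- "threshold_on_limit"
    return(fit)
  }
  fit$valid <- TRUE
  fit$invalid_reason <- NA_character_
  fit$threshold_corrected <- thr
  fit
}

#' @export
print.psyfit <- function(x, ...) {
  cat("Psychometric fit (", x$sigmoid, ")\n", sep = "")
  if (!is.null(x$params)) {
    cat(
      "  m = ", format(x$params$m, digits = 5),
      ", w = ", format(x$params$w, digits = 5),
      ", gamma = ", format(x$params$gamma, digits = 3),
      ", delta = ", format(x$params$delta, digits = 3), "\n",
      sep = ""
    )
    cat("  -logL = ", format(x$neg_log_lik, digits = 7), "\n", sep = "")
  }
  if (isTRUE(x$valid)) {
    cat("  valid; corrected threshold = ",
        format(x$threshold_corrected, digits = 5), "\n", sep = "")
  } else {
    cat("  invalid (", x$invalid_reason, ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy a psychometric fit
#'
#' @param x A `psyfit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.psyfit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(
    term = c("m", "w", "gamma", "delta"),
    estimate = c(x$params$m, x$params$w, x$params$gamma, x$params$delta)
  )
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psyfit` object.
#' @param ... Unused.
#' @return A one-row tibble: `neg_log_lik`, `valid`, `invalid_reason`,
#'   `threshold_corrected`, `n_levels`, `n_trials`.
#' @export
glance.psyfit <- function(x, ...) {
  tibble::tibble(
    neg_log_lik = x$neg_log_lik,
    valid = x$valid,
    invalid_reason = x$invalid_reason,
    threshold_corrected = x$threshold_corrected,
    n_levels = nrow(x$data),
    n_trials = sum(x$data$n)
  )
}

#' Read a (level, n, k) response table from CSV
#'
#' Accepts either an aggregated table with columns `level`, `n`, `k`, or a raw
#' trial table with columns `level` and `response_yes` which is aggregated.
#'
#' @param path CSV path.
#' @return A tibble with columns `level`, `n`, `k`.
#' @export
read_binomial_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("level", "n", "k") %in% names(x))) {
    binomial_data(x$level, x$n, x$k)
  } else if (all(c("level", "response_yes") %in% names(x))) {
    agg <- x |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(
        n = dplyr::n(), k = sum(.data$response_yes), .groups = "drop"
      ) |>
      dplyr::arrange(.data$level)
    binomial_data(agg$level, agg$n, agg$k)
  } else {
    stop("expected columns (level, n, k) or (level, response_yes)", call. = FALSE)
  }
}
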