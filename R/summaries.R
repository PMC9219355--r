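#' Exact Clopper-Pearson binomial confidence bounds
#'
#' Conservative exact bounds from Beta quantiles: the two-sided interval at
#' confidence `conf` is `(qbeta(a/2, k, n-k+1), qbeta(1-a/2, k+1, n-k))` with
#' `a = 1 - conf`, with the closed-form edges `lower = 0` at `k = 0` and
#' `upper = 1` at `k = n`. The one-sided variant returns the lower bound at
#' confidence `conf` (upper fixed at 1).
#'
#' @param k Successes (vectorized), `0 <= k <= n`.
#' @param n Trials, `n >= 1`.
#' @param conf Confidence level (default 0.99, the reporting convention used
#'   throughout the package).
#' @param sides `"two"` (default) or `"one"` (lower bound only).
#' @return A tibble with `lower` and `upper` columns (fractions).
#' @examples
#' clopper_pearson(124, 670)          # ~ (0.148, 0.227)
#' clopper_pearson(5, 5, conf = 0.999, sides = "one")
#' @export
clopper_pearson <- function(k, n, conf = 0.99, sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(k < 0 | k > n)) stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  stopifnot(conf > 0, conf < 1)
  alpha <- 1 - conf
  a_lo <- if (sides == "two") alpha / 2 else alpha
  lower <- ifelse(k == 0, 0, qbeta(a_lo, k, n - k + 1))
  upper <- if (sides == "two") {
    ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  } else {
    rep(1, length(lower))
  }
  tibble::tibble(lower = lower, upper = upper)
}

#' Šidák-adjusted per-comparison confidence level
#'
#' For `m` statistically independent comparisons, the per-comparison alpha
#' achieving a family-wise error rate `fwer` is `1 - (1 - fwer)^(1/m)`; the
#' returned confidence is its complement, `(1 - fwer)^(1/m)`.
#'
#' @param m Number of comparisons (>= 1).
#' @param fwer Family-wise error rate, in (0, 1).
#' @return Per-comparison confidence level (fraction).
#' @examples
#' sidak_level(50, 0.05) # ~0.99897, i.e. the 99.9% level
#' @export
sidak_level <- function(m, fwer = 0.05) {
  if (!is.numeric(fwer) || any(fwer <= 0) || any(fwer >= 1)) {
    stop("`fwer` must be in (0, 1)", call. = FALSE)
  }
  if (any(m < 1)) stop("`m` must be >= 1", call. = FALSE)
  (1 - fwer)^(1 / m)
}

#' Summarise feasibility flags into table rows
#'
#' Aggregates a per-case classification into one row per stratum and
#' supervision level (`single`, `two_best`, `two_least`, `three`): the
#' denominator `n` (cases in the policy's denominator), count `k`, percentage,
#' and exact two-sided Clopper-Pearson bounds. Within any stratum the
#' percentages are ordered `single >= two_best >= two_least >= three` because
#' the per-case flags are nested.
#'
#' @param results A [classify_cases()] result.
#' @param by Character vector of grouping columns (default `"facility"`).
#' @param conf Confidence level (default 0.99).
#' @return A tibble of class `break_summary`: grouping columns, `window`
#'   (policy label), `measure`, `n`, `k`, `pct`, `ci_low`, `ci_high`
#'   (percent scale). Strata with `n = 0` keep `NA` statistics.
#' @examples
#' st <- generate_study(1, hist_days = 20, future_days = 2)
#' b <- lower_prediction_bound(fit_procedure_stats(st$historical))
#' summarize_feasibility(classify_cases(st$future, b,
#'                                      default_policies()$lunch))
#' @export
summarize_feasibility <- function(results, by = "facility", conf = 0.99) {
  policy <- attr(results, "policy")
  measures <- c("single", "two_best", "two_least", "three")
  out <- tibble::as_tibble(results) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = sum(.data$in_denominator),
      dplyr::across(dplyr::all_of(measures),
                    ~ sum(.x & .data$in_denominator, na.rm = TRUE),
                    .names = "k_{.col}"),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::starts_with("k_"), names_to = "measure",
                        names_prefix = "k_", values_to = "k") |>
    dplyr::mutate(measure = factor(.data$measure, levels = measures)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(by)), .data$measure)
  ci <- dplyr::bind_rows(lapply(seq_len(nrow(out)), function(i) {
    if (out$n[i] == 0) return(tibble::tibble(lower = NA_real_,
                                             upper = NA_real_))
    clopper_pearson(out$k[i], out$n[i], conf = conf)
  }))
  out <- dplyr::mutate(out,
    window = if (!is.null(policy)) policy$label else NA_character_,
    pct = ifelse(.data$n > 0, 100 * .data$k / .data$n, NA_real_),
    ci_low = 100 * ci$lower, ci_high = 100 * ci$upper
  ) |>
    dplyr::relocate("window", .after = dplyr::all_of(by[length(by)]))
  class(out) <- c("break_summary", class(out))
  out
}

#' Šidák-corrected stratum lower confidence limits
#'
#' Service-by-weekday staff-scheduling analysis for one facility: strata with
#' at least `min_n` cases are retained; within each, `k` counts cases whose
#' suitable interval is at least the break duration (single-room, any time of
#' day); the one-sided Clopper-Pearson lower limit is computed at the
#' Šidák-adjusted confidence for the realized number of strata, holding the
#' family-wise error rate at `fwer`.
#'
#' @param results A [classify_cases()] result for one facility.
#' @param fwer Family-wise error rate (default 0.05).
#' @param min_n Minimum stratum size (default 5).
#' @return A tibble: `service`, `weekday`, `n`, `k`, `pct`, `lower_limit`
#'   (percent), plus the shared `conf_level` and `n_strata`.
#' @export
stratum_lower_limits <- function(results, fwer = 0.05, min_n = 5) {
  policy <- attr(results, "policy")
  dur <- policy$duration_min
  strata <- tibble::as_tibble(results) |>
    dplyr::filter(.data$usable) |>
    dplyr::group_by(.data$service, .data$weekday) |>
    dplyr::summarise(
      n = dplyr::n(),
      k = sum(!.data$int_empty & .data$int_end - .data$int_start >= dur),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_n)
  if (nrow(strata) == 0) {
    return(dplyr::mutate(strata, pct = numeric(0), lower_limit = numeric(0),
                         conf_level = numeric(0), n_strata = integer(0)))
  }
  conf <- sidak_level(nrow(strata), fwer)
  lo <- clopper_pearson(strata$k, strata$n, conf = conf, sides = "one")$lower
  dplyr::mutate(strata, pct = 100 * .data$k / .data$n,
                lower_limit = 100 * lo, conf_level = conf,
                n_strata = nrow(strata))
}

#' Facility covariate analysis
#'
#' Relates each facility-and-window feasibility result (`y`, the single-room
#' feasibility percentage) to the facility's percentage of denominator cases
#' whose actual surgical time was at least the break duration plus the
#' lead-in (`x`). `y <= x` must hold pointwise: the prediction-bound
#' truncation can only shrink feasibility relative to durations known in
#' retrospect. Pearson and Spearman correlations (on percentages, average
#' ranks for ties) are reported per break duration when at least 3 points are
#' available.
#'
#' @param results_list A list of [classify_cases()] results (one per
#'   policy), e.g. the `results` element of [run_study()].
#' @return A list of class `facility_covariate` with `points` (tibble:
#'   `facility`, `window`, `duration_min`, `x`, `y`) and `correlations`
#'   (tibble: `duration_min`, `n_points`, `pearson`, `spearman`).
#' @export
facility_covariate <- function(results_list) {
  points <- dplyr::bind_rows(lapply(results_list, function(res) {
    policy <- attr(res, "policy")
    need_h <- (policy$duration_min + policy$lead_in_min) / 60
    tibble::as_tibble(res) |>
      dplyr::filter(.data$in_denominator) |>
      dplyr::group_by(.data$facility) |>
      dplyr::summarise(
        window = policy$label,
        duration_min = policy$duration_min,
        n = dplyr::n(),
        x = 100 * mean(.data$hours >= need_h),
        y = 100 * mean(.data$single),
        .groups = "drop"
      )
  }))
  correlations <- points |>
    dplyr::group_by(.data$duration_min) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      pearson = if (dplyr::n() >= 3) cor(.data$x, .data$y) else NA_real_,
      spearman = if (dplyr::n() >= 3) {
        cor(.data$x, .data$y, method = "spearman")
      } else NA_real_,
      .groups = "drop"
    )
  structure(list(points = points, correlations = correlations),
            class = "facility_covariate")
}

#' @export
print.facility_covariate <- function(x, ...) {
  cat("<facility_covariate> ", nrow(x$points), " facility-window points\n",
      sep = "")
  print(x$correlations)
  invisible(x)
}
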