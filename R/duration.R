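#' Per-procedure log-normal summary statistics
#'
#' For each procedure code, summarises the historical surgical times on the
#' natural-log hour scale: the count of cases used `n`, the sample mean `m`,
#' and the sample SD `s` of the log times. When a code has more than `cap`
#' historical cases, only the most recent `cap` (by `surgery_start`,
#' descending; ties broken by stable input order) contribute. Codes with
#' fewer than two cases are flagged `insufficient` (`s` is undefined), and a
#' code absent from the history yields an `n = 0` row rather than an error.
#'
#' @param historical A case tibble (see [generate_schedule()] for the
#'   columns).
#' @param codes Optional character vector: return exactly these codes,
#'   including `n = 0` rows for codes with no history. Default: every code in
#'   `historical`.
#' @param cap Maximum number of most-recent cases used per code (default 99).
#' @return A tibble: `code`, `n`, `m`, `s`, `insufficient`.
#' @examples
#' st <- generate_study(1, hist_days = 10, future_days = 0)
#' head(fit_procedure_stats(st$historical))
#' @export
fit_procedure_stats <- function(historical, codes = NULL, cap = 99L) {
  stopifnot(cap >= 1)
  stats <- historical |>
    dplyr::mutate(.log_h = log(surgical_hours(historical)),
                  .row = dplyr::row_number()) |>
    dplyr::group_by(.data$code) |>
    dplyr::arrange(dplyr::desc(.data$surgery_start), .data$.row,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = cap) |>
    dplyr::summarise(
      n = dplyr::n(),
      m = mean(.data$.log_h),
      s = ifelse(dplyr::n() >= 2, sd(.data$.log_h), NA_real_),
      .groups = "drop"
    )
  if (!is.null(codes)) {
    stats <- tibble::tibble(code = unique(codes)) |>
      dplyr::left_join(stats, by = "code") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  }
  dplyr::mutate(stats, insufficient = .data$n < 2)
}

#' Student-t lower prediction bound of a single future surgical time
#'
#' Computes, per procedure, the lower prediction bound for one future
#' observation: a value that the next randomly selected surgical time will
#' exceed with probability `1 - risk`. On the log scale this is
#' `m - t(1 - risk, n - 1) * s * sqrt(1 + 1/n)`, exponentiated back to hours.
#' Codes with `n < 2` get an unusable result (`usable = FALSE`, `bound_hours`
#' `NA`); downstream analyses exclude those cases and report the exclusion.
#'
#' @param stats Output of [fit_procedure_stats()].
#' @param risk Lower-tail risk (default 0.05 for a 5% lower bound).
#' @return A tibble: `code`, `n`, `bound_hours`, `usable`.
#' @examples
#' s <- tibble::tibble(code = "X", n = 99L, m = log(2), s = 0.5,
#'                     insufficient = FALSE)
#' lower_prediction_bound(s)$bound_hours # ~0.868 h
#' @export
lower_prediction_bound <- function(stats, risk = 0.05) {
  stopifnot(is.numeric(risk), length(risk) == 1, risk > 0, risk < 1)
  usable <- stats$n >= 2 & is.finite(stats$s)
  bound <- rep(NA_real_, nrow(stats))
  if (any(usable)) {
    n <- stats$n[usable]
    bound[usable] <- exp(stats$m[usable] -
                           qt(1 - risk, df = n - 1) * stats$s[usable] *
                           sqrt(1 + 1 / n))
  }
  tibble::tibble(code = stats$code, n = stats$n,
                 bound_hours = bound, usable = usable)
}

#' Match future cases to their procedure prediction bounds
#'
#' Joins per-code prediction bounds onto a future case table and labels why a
#' case has no usable bound: `"no_history"` when the code never occurred in
#' the historical period, `"insufficient_history"` when it occurred fewer
#' than two times.
#'
#' @param future A future-period case tibble.
#' @param bounds Output of [lower_prediction_bound()].
#' @return `future` with `case_id`, `hours` (actual surgical time),
#'   `bound_hours`, `usable`, and `excluded_reason` columns.
#' @export
case_bounds <- function(future, bounds) {
  add_case_ids(future) |>
    dplyr::left_join(
      dplyr::select(bounds, "code", "bound_hours", "usable", hist_n = "n"),
      by = "code"
    ) |>
    dplyr::mutate(
      hours = as.numeric(.data$surgery_end - .data$surgery_start,
                         units = "hours"),
      usable = dplyr::coalesce(.data$usable, FALSE),
      excluded_reason = dplyr::case_when(
        is.na(.data$hist_n) ~ "no_history",
        !.data$usable ~ "insufficient_history",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select(-"hist_n")
}

#' Realized coverage of the lower prediction bounds
#'
#' The fraction of future cases whose actual surgical time fell strictly
#' below their procedure's lower prediction bound, with an exact 99%
#' Clopper-Pearson interval. Under a correctly specified log-normal model
#' this incidence should sit near the nominal bound risk.
#'
#' @param cases_with_bounds Output of [case_bounds()] (only `usable` cases
#'   contribute).
#' @param conf Confidence level of the interval (default 0.99).
#' @return A one-row tibble: `n`, `k`, `incidence`, `ci_low`, `ci_high`
#'   (fractions).
#' @export
coverage_check <- function(cases_with_bounds, conf = 0.99) {
  u <- dplyr::filter(cases_with_bounds, .data$usable)
  if (nrow(u) == 0) {
    stop("no future cases with a usable prediction bound; incidence undefined",
         call. = FALSE)
  }
  k <- sum(u$hours < u$bound_hours)
  ci <- clopper_pearson(k, nrow(u), conf = conf)
  tibble::tibble(n = nrow(u), k = k, incidence = k / nrow(u),
                 ci_low = ci$lower, ci_high = ci$upper)
}

#' Monte-Carlo calibration of the prediction bound
#'
#' Repeatedly draws a history of `n_hist` log-normal surgical times and one
#' future time from the same distribution, computes the lower prediction
#' bound from the history via [lower_prediction_bound()], and records whether
#' the future time fell below the bound. With the t-based bound the expected
#' incidence equals the nominal `risk` exactly.
#'
#' @param n_rep Number of replicates (default 100,000).
#' @param n_hist Historical sample size per replicate (default 99, the
#'   history cap).
#' @param mu,sigma Log-scale mean and SD of the surgical-time distribution
#'   (log-hours).
#' @param risk Bound risk (default 0.05).
#' @param seed Integer seed.
#' @return A one-row tibble: `n_rep`, `k`, `incidence`.
#' @examples
#' calibration_simulation(n_rep = 2000, seed = 1)
#' @export
calibration_simulation <- function(n_rep = 1e5, n_hist = 99, mu = log(2),
                                   sigma = 0.5, risk = 0.05, seed = 1L) {
  stopifnot(n_rep >= 1, n_hist >= 2)
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_rep * n_hist, mu, sigma), nrow = n_hist)
    m <- colMeans(x)
    s <- sqrt(colSums((x - rep(m, each = n_hist))^2) / (n_hist - 1))
    future <- rnorm(n_rep, mu, sigma)
    stats <- tibble::tibble(code = as.character(seq_len(n_rep)),
                            n = n_hist, m = m, s = s, insufficient = FALSE)
    b <- lower_prediction_bound(stats, risk = risk)
    k <- sum(exp(future) < b$bound_hours)
    tibble::tibble(n_rep = n_rep, k = k, incidence = k / n_rep)
  })
}
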