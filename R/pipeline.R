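#' Run the full break-feasibility study on synthetic data
#'
#' Generates a seeded historical/future study, fits per-procedure log-normal
#' statistics with the 99-case history cap, computes 5% lower prediction
#' bounds, classifies every future case under each policy, and aggregates
#' per-facility summary rows with 99% Clopper-Pearson intervals. Also runs
#' the bound coverage check and the facility covariate analysis.
#'
#' @param seed Integer seed for the synthetic study.
#' @param hist_days,future_days Weekday counts (defaults: three years and
#'   one year of weekdays).
#' @param policies Named list of [break_policy()] objects (default
#'   [default_policies()]).
#' @param risk Prediction-bound risk used for the shared bound fit.
#' @return An object of class `break_study`: a list with `historical`,
#'   `future`, `archetypes`, `stats`, `bounds`, `results` (named list of
#'   [classify_cases()] outputs), `summary` (combined [summarize_feasibility()]
#'   rows), `coverage`, `covariate`, `policies`, and `seed`.
#' @examples
#' study <- run_study(seed = 1, hist_days = 20, future_days = 3)
#' study
#' @export
run_study <- function(seed = 1L, hist_days = 756L, future_days = 252L,
                      policies = default_policies(), risk = 0.05) {
  tables <- generate_study(seed = seed, hist_days = hist_days,
                           future_days = future_days)
  stats <- fit_procedure_stats(tables$historical)
  bounds <- lower_prediction_bound(stats, risk = risk)
  results <- lapply(policies, function(p) {
    classify_cases(tables$future, bounds, p)
  })
  summary <- dplyr::bind_rows(lapply(results, summarize_feasibility))
  structure(
    list(historical = tables$historical, future = tables$future,
         archetypes = tables$archetypes, stats = stats, bounds = bounds,
         results = results, summary = summary,
         coverage = coverage_check(case_bounds(tables$future, bounds)),
         covariate = facility_covariate(results),
         policies = policies, seed = seed),
    class = "break_study"
  )
}

#' @export
print.break_study <- function(x, ...) {
  cat("<break_study> seed ", x$seed, ": ", nrow(x$historical),
      " historical and ", nrow(x$future), " future cases, ",
      length(x$policies), " policies\n", sep = "")
  cat("Bound coverage: ", sprintf("%.2f%% (99%% CI %.2f-%.2f)",
      100 * x$coverage$incidence, 100 * x$coverage$ci_low,
      100 * x$coverage$ci_high), "\n\n", sep = "")
  cat(format_summary_table(x$summary), sep = "\n")
  invisible(x)
}

#' @describeIn run_study One row per future case and policy, with the four
#'   feasibility flags in long form.
#' @param x A `break_study`.
#' @param ... Unused.
#' @method tidy break_study
#' @export
tidy.break_study <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$results), function(nm) {
    dplyr::mutate(tibble::as_tibble(x$results[[nm]]), policy = nm,
                  window = attr(x$results[[nm]], "policy")$label,
                  .before = 1)
  }))
}

#' @describeIn run_study One-row overview: case counts, procedure codes,
#'   exclusions, and realized bound coverage.
#' @method glance break_study
#' @export
glance.break_study <- function(x, ...) {
  first <- x$results[[1]]
  tibble::tibble(
    seed = x$seed,
    n_historical = nrow(x$historical),
    n_future = nrow(x$future),
    n_codes = nrow(x$stats),
    n_excluded = sum(!first$usable),
    coverage_pct = 100 * x$coverage$incidence
  )
}

#' Render summary rows in the table cell format
#'
#' Formats each stratum row as `"pct (lo, hi)"` cells (one decimal, half
#' away from zero) across the four supervision levels, matching the layout
#' of the feasibility tables.
#'
#' @param summary A [summarize_feasibility()] result (or several row-bound
#'   together).
#' @return Character vector of formatted lines.
#' @export
format_summary_table <- function(summary) {
  by <- setdiff(names(summary),
                c("window", "measure", "n", "k", "pct", "ci_low", "ci_high"))
  wide <- summary |>
    dplyr::mutate(cell = format_pct_cell(.data$pct, .data$ci_low,
                                         .data$ci_high)) |>
    dplyr::select(dplyr::all_of(by), "window", "n", "measure", "cell") |>
    tidyr::pivot_wider(names_from = "measure", values_from = "cell")
  for (m in c("single", "two_best", "two_least", "three")) {
    if (!m %in% names(wide)) wide[[m]] <- ""
  }
  if (any(wide$n == 0)) {
    warning("strata with n = 0 rendered as blank cells", call. = FALSE)
  }
  header <- c("Location", "Window", "n", "Single cases",
              "Two rooms, best chance", "Two rooms, least chance",
              "Three rooms")
  rows <- cbind(
    apply(wide[, by, drop = FALSE], 1, paste, collapse = " / "),
    wide$window, format(wide$n),
    as.matrix(wide[, c("single", "two_best", "two_least", "three")])
  )
  tab <- rbind(header, rows)
  for (j in seq_len(ncol(tab))) {
    tab[, j] <- formatC(tab[, j], width = max(nchar(tab[, j])), flag = "-")
  }
  unname(apply(tab, 1, paste, collapse = "  "))
}

write_meta <- function(path, cfg) {
  writeLines(c("# orbreaks run metadata", format_run_config(cfg)), path)
}

#' Pipeline commands
#'
#' File-based entry points chaining the pipeline stages; each writes CSV
#' outputs under `out_dir` and logs progress to stderr. `cmd_simulate`
#' writes `historical.csv`, `future.csv`, and run metadata. `cmd_analyze`
#' reads two case CSVs, fits bounds, classifies every policy in the config,
#' and writes per-case results, summary rows, the pediatric-facility
#' service-by-weekday stratum limits, the facility covariate report, and the
#' coverage check. `cmd_report` renders a summary CSV as formatted text
#' tables, and `cmd_full_run` chains all three.
#'
#' @param config A run configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param historical_csv,future_csv Case CSV paths.
#' @param summary_csv Summary CSV path as written by `cmd_analyze`.
#' @return `cmd_simulate`/`cmd_analyze` return the output paths invisibly;
#'   `cmd_report` returns the formatted lines invisibly (after printing).
#' @export
cmd_simulate <- function(config = default_run_config(),
                         out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir,
                                 call. = FALSE)
  tables <- generate_study(seed = config$seed, hist_days = config$hist_days,
                           future_days = config$future_days)
  paths <- file.path(out_dir, c("historical.csv", "future.csv",
                                "run_metadata.txt"))
  write_case_table(tables$historical, paths[1])
  write_case_table(tables$future, paths[2])
  write_meta(paths[3], config)
  message("wrote ", nrow(tables$historical), " historical and ",
          nrow(tables$future), " future cases to ", out_dir)
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(historical_csv, future_csv,
                        config = default_run_config(),
                        out_dir = config$out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  historical <- read_case_table(historical_csv)
  future <- read_case_table(future_csv)
  policies <- config_policies(config)
  stats <- fit_procedure_stats(historical)
  bounds <- lower_prediction_bound(stats, risk = config$risk)
  readr::write_csv(stats, file.path(out_dir, "procedure_stats.csv"),
                   progress = FALSE)
  readr::write_csv(bounds, file.path(out_dir, "bounds.csv"),
                   progress = FALSE)

  results <- lapply(policies, function(p) classify_cases(future, bounds, p))
  for (nm in names(results)) {
    res <- results[[nm]]
    message(sprintf(
      "policy %s: %d cases; %d excluded (no usable bound: %s); %d outside denominator",
      nm, nrow(res), sum(!res$usable),
      paste(names(table(res$excluded_reason)),
            table(res$excluded_reason), sep = "=", collapse = ", "),
      sum(res$usable & !res$in_denominator)))
    readr::write_csv(
      dplyr::select(tibble::as_tibble(res), "case_id", "facility", "date",
                    "room", "single", "two_best", "two_least", "three",
                    "excluded_reason", "in_denominator"),
      file.path(out_dir, paste0("case_results_", nm, ".csv")),
      progress = FALSE)
  }
  summary <- dplyr::bind_rows(lapply(results, summarize_feasibility))
  readr::write_csv(summary, file.path(out_dir, "summary.csv"),
                   progress = FALSE)

  # staff-scheduling strata: middle-sized facility, 30-minute break anytime
  counts <- sort(table(future$facility))
  mid_fac <- names(counts)[ceiling(length(counts) / 2)]
  mid <- classify_cases(dplyr::filter(future, .data$facility == mid_fac),
                        bounds, break_policy(30, risk = config$risk))
  strata <- dplyr::mutate(stratum_lower_limits(mid), facility = mid_fac,
                          .before = 1)
  readr::write_csv(strata, file.path(out_dir, "strata.csv"),
                   progress = FALSE)

  cov <- facility_covariate(results)
  readr::write_csv(cov$points, file.path(out_dir, "covariate_points.csv"),
                   progress = FALSE)
  readr::write_csv(cov$correlations,
                   file.path(out_dir, "covariate_correlations.csv"),
                   progress = FALSE)
  readr::write_csv(coverage_check(case_bounds(future, bounds)),
                   file.path(out_dir, "coverage.csv"), progress = FALSE)
  invisible(file.path(out_dir, "summary.csv"))
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(summary_csv) {
  if (!file.exists(summary_csv)) stop("no such file: ", summary_csv,
                                      call. = FALSE)
  summary <- readr::read_csv(summary_csv, show_col_types = FALSE,
                             progress = FALSE) |>
    dplyr::mutate(measure = factor(.data$measure,
                                   levels = c("single", "two_best",
                                              "two_least", "three")))
  lines <- format_summary_table(summary)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @rdname cmd_simulate
#' @export
cmd_full_run <- function(config = default_run_config(),
                         out_dir = config$out_dir) {
  paths <- cmd_simulate(config, out_dir)
  summary_csv <- cmd_analyze(paths[1], paths[2], config, out_dir)
  cmd_report(summary_csv)
}
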