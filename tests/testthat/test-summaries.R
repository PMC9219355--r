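test_that("Clopper-Pearson bounds match closed forms and an independent oracle", {
  # zero-success and all-success closed forms
  ci <- clopper_pearson(0, 10)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 1 - 0.005^(1 / 10), tolerance = 1e-12)
  ci <- clopper_pearson(10, 10)
  expect_equal(ci$upper, 1)
  expect_equal(ci$lower, 0.005^(1 / 10), tolerance = 1e-12)
  # one-sided zero-failure closed form at the 99.9% level
  expect_equal(clopper_pearson(5, 5, conf = 0.999, sides = "one")$lower,
               0.001^(1 / 5), tolerance = 1e-12)

  # independent oracle: stats::binom.test exact interval, 6+ significant digits
  withr::with_seed(17, {
    for (i in 1:40) {
      n <- sample(1:2000, 1)
      k <- sample(0:n, 1)
      conf <- sample(c(0.9, 0.95, 0.99), 1)
      want <- stats::binom.test(k, n, conf.level = conf)$conf.int
      got <- clopper_pearson(k, n, conf = conf)
      expect_equal(got$lower, want[1], tolerance = 1e-7)
      expect_equal(got$upper, want[2], tolerance = 1e-7)
    }
  })

  expect_error(clopper_pearson(1, 0), ">= 1")
  expect_error(clopper_pearson(5, 4), "0 <= k <= n")
  # the interval always contains k/n
  ci <- clopper_pearson(c(0, 3, 124, 670), c(10, 10, 670, 670))
  expect_true(all(ci$lower <= c(0, 3, 124, 670) / c(10, 10, 670, 670)))
  expect_true(all(ci$upper >= c(0, 3, 124, 670) / c(10, 10, 670, 670)))
})

test_that("the Sidak per-comparison level reproduces its closed forms", {
  expect_equal(1 - sidak_level(1, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(1 - sidak_level(2, 0.05), 1 - sqrt(0.95), tolerance = 1e-12)
  expect_equal(1 - sidak_level(50, 0.05), 0.00102534, tolerance = 1e-6)
  # decreasing per-comparison alpha, i.e. increasing confidence, in m
  levels <- sidak_level(c(1, 2, 5, 50, 500), 0.05)
  expect_true(all(diff(levels) > 0))
  expect_error(sidak_level(10, 1.5), "fwer")
  expect_error(sidak_level(0, 0.05), "m")
})

test_that("summary rows carry exact intervals and the nested column ordering", {
  cases <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_case(i, 600, 800, sprintf("A%d", i))
  }))
  bounds <- make_bounds(unique(cases$code), bound_min = 240)
  res <- classify_cases(cases, bounds, break_policy(30))
  sm <- summarize_feasibility(res)
  single <- sm[sm$measure == "single", ]
  expect_equal(single$n, 10)
  expect_equal(single$pct, 100)
  expect_equal(single$ci_low, 100 * 0.005^(1 / 10), tolerance = 1e-9)
  expect_equal(single$ci_high, 100)
  # left-to-right ordering of every summary row block
  ord <- sm |>
    dplyr::group_by(facility) |>
    dplyr::summarise(ok = all(diff(pct) <= 0))
  expect_true(all(ord$ok))
})

test_that("empty strata yield blank rows rather than errors", {
  cases <- make_case(1, 480, 500, "A") # 20-minute case, bound 20 min
  bounds <- make_bounds("A", bound_min = 20)
  res <- classify_cases(cases, bounds,
                        break_policy(30, window_start = "11:15",
                                     window_end = "12:45"))
  sm <- summarize_feasibility(res)
  expect_equal(unique(sm$n), 0)
  expect_true(all(is.na(sm$pct)))
  expect_true(all(is.na(sm$ci_low)))
})

test_that("stratum limits use the realized Sidak level and the n >= 5 rule", {
  # one service, five weekdays with 6 cases each, plus one sparse weekday-like
  # stratum via a second service with only 4 cases
  days <- rep(MONDAY + 0:4, each = 6)
  cases <- dplyr::bind_rows(lapply(seq_along(days), function(i) {
    make_case(1, 600, 800, sprintf("C%02d", i), date = days[i])
  }))
  sparse <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_case(2, 600, 800, sprintf("S%02d", i), service = "rare")
  }))
  all_cases <- dplyr::bind_rows(cases, sparse)
  bounds <- make_bounds(unique(all_cases$code), bound_min = 240)
  res <- classify_cases(all_cases, bounds, break_policy(30))
  lim <- stratum_lower_limits(res)
  expect_equal(nrow(lim), 5) # the n = 4 stratum is dropped
  expect_false("rare" %in% lim$service)
  expect_equal(unique(lim$n_strata), 5)
  # per-stratum alpha = 1 - 0.95^(1/5)
  expect_equal(unique(lim$conf_level), 0.95^(1 / 5), tolerance = 1e-12)
  # suitable interval 615-840 (bound 240): 225 min >= 30, all feasible
  expect_equal(lim$k, lim$n)
  # zero-failure one-sided closed form: alpha^(1/n) at alpha = 1 - 0.95^(1/5)
  expect_equal(unique(lim$lower_limit),
               100 * (1 - 0.95^(1 / 5))^(1 / 6), tolerance = 1e-9)
})

test_that("facility covariate points bound feasibility and tolerate ties", {
  st <- generate_study(seed = 9, hist_days = 20, future_days = 4)
  bounds <- lower_prediction_bound(fit_procedure_stats(st$historical))
  results <- lapply(default_policies()[c("lunch", "lunch_anytime",
                                         "morning")], function(p) {
    classify_cases(st$future, bounds, p)
  })
  cov <- facility_covariate(results)
  expect_true(all(cov$points$y <= cov$points$x + 1e-9))
  expect_equal(nrow(cov$points), 9) # 3 facilities x 3 windows
  cor30 <- cov$correlations[cov$correlations$duration_min == 30, ]
  expect_equal(cor30$n_points, 6)
  expect_false(is.na(cor30$pearson))

  # fewer than 3 points per duration: correlation reported as NA, not an error
  one_fac <- dplyr::filter(st$future, facility == "ambulatory")
  cov1 <- facility_covariate(list(classify_cases(one_fac, bounds,
                                                 default_policies()$lunch)))
  expect_equal(cov1$correlations$n_points, 1)
  expect_true(is.na(cov1$correlations$pearson))

  # duplicated policies produce exactly tied points; Spearman (average
  # ranks) must still come back finite
  tied <- facility_covariate(c(results["lunch"], dup = results["lunch"]))
  cor30_tied <- tied$correlations[tied$correlations$duration_min == 30, ]
  expect_true(is.finite(cor30_tied$spearman))
})
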