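lunch <- break_policy(30, window_start = "11:15", window_end = "12:45")

test_that("the suitable interval runs from lead-in end to predicted-or-actual end", {
  pol <- break_policy(30)
  # bound shorter than the case: interval ends at start + bound
  c1 <- make_case(1, 480, 630, "A") |> # 08:00-10:30
    dplyr::mutate(bound_hours = 2, usable = TRUE)
  iv <- suitable_interval(c1, pol)
  expect_equal(c(iv$int_start, iv$int_end), c(495, 600)) # 08:15-10:00
  # case finished sooner than predicted: interval ends at the actual end
  c2 <- make_case(1, 480, 570, "A") |> # 08:00-09:30
    dplyr::mutate(bound_hours = 2, usable = TRUE)
  iv <- suitable_interval(c2, pol)
  expect_equal(c(iv$int_start, iv$int_end), c(495, 570))
  # bound shorter than the lead-in: empty interval
  c3 <- dplyr::mutate(c1, bound_hours = 0.2)
  expect_true(suitable_interval(c3, pol)$int_empty)
  # unusable bounds must be filtered by the caller
  expect_error(suitable_interval(dplyr::mutate(c1, usable = FALSE), pol),
               "usable")
})

test_that("the stricter bound-end reading subtracts the lead-in", {
  pol_b <- break_policy(30, bound_end_rule = "subtract_lead_in")
  c1 <- make_case(1, 480, 630, "A") |>
    dplyr::mutate(bound_hours = 2, usable = TRUE)
  iv <- suitable_interval(c1, pol_b)
  expect_equal(c(iv$int_start, iv$int_end), c(495, 585)) # end = 10:00 - 15 min
})

test_that("room adjacency is cyclic over the rooms present", {
  expect_equal(unname(adjacent_rooms(1, 1:10)), c(10, 2))
  expect_equal(unname(adjacent_rooms(2, c(1, 2, 3))), c(1, 3))
  expect_equal(unname(adjacent_rooms(1, c(1, 2))), c(2, 2))
  expect_equal(unname(adjacent_rooms(7, 7)), c(7, 7))
  # unsorted input and gaps in numbering are fine
  expect_equal(unname(adjacent_rooms(5, c(9, 2, 5))), c(2, 9))
  expect_error(adjacent_rooms(4, c(1, 2)), "not among")
})

test_that("overlap with a neighbor room picks the longest single intersection", {
  idx <- c(495, 720)
  expect_equal(overlap_with_room(idx, tibble::tibble(int_start = 540,
                                                     int_end = 660)),
               c(540, 660))
  expect_equal(overlap_with_room(idx, NULL), idx)
  expect_equal(overlap_with_room(idx, tibble::tibble(int_start = numeric(),
                                                     int_end = numeric())),
               idx)
  # no intersection at all: treated as best chance, full index interval
  expect_equal(overlap_with_room(idx, tibble::tibble(int_start = 730,
                                                     int_end = 800)), idx)
  # two candidates: 90-minute intersection beats 30-minute
  nb <- tibble::tibble(int_start = c(510, 600), int_end = c(540, 690))
  expect_equal(overlap_with_room(idx, nb), c(600, 690))
  # tie in length goes to the earlier intersection
  nb_tie <- tibble::tibble(int_start = c(600, 500), int_end = c(660, 560))
  expect_equal(overlap_with_room(idx, nb_tie), c(500, 560))
})

test_that("window feasibility matches a minute-grid search", {
  expect_true(break_feasible(495, 720, lunch))   # break 11:15-11:45 fits
  expect_false(break_feasible(495, 495, lunch))  # empty interval
  expect_true(break_feasible(760, 810, lunch))   # start 12:40, in window
  expect_false(break_feasible(770, 840, lunch))  # earliest start after 12:45
  anytime <- break_policy(30)
  expect_true(break_feasible(0, 30, anytime))
  expect_false(break_feasible(0, 29, anytime))

  withr::with_seed(101, {
    for (i in 1:200) {
      pol <- random_policy()
      lo <- sample(400:900, 1)
      hi <- lo + sample(-10:300, 1)
      got <- break_feasible(lo, hi, pol)
      want <- if (hi <= lo) FALSE else oracle_fits(lo, hi, pol)
      expect_identical(got, want)
    }
  })
})

test_that("a case with empty adjacent rooms is limited only by itself", {
  cases <- make_case(3, 600, 800, "A")
  bounds <- make_bounds("A", bound_min = 240)
  res <- classify_cases(cases, bounds, lunch)
  expect_true(all(c(res$single, res$two_best, res$two_least, res$three)))
  # neighbors present but with no case overlapping the suitable interval
  cases2 <- make_cases(make_case(3, 600, 800, "A"),
                       make_case(2, 900, 960, "B"),
                       make_case(4, 900, 960, "C"))
  bounds2 <- make_bounds(c("A", "B", "C"), bound_min = c(240, 30, 30))
  res2 <- classify_cases(cases2, bounds2, lunch)
  r <- res2[res2$code == "A", ]
  expect_true(all(c(r$single, r$two_best, r$two_least, r$three)))
})

test_that("asymmetric neighbor overlaps split best from least chance", {
  # index room 2 (08:00-13:00, long bound); room 1 overlaps 90 min inside the
  # window; room 3 overlaps only 20 min of the suitable interval
  cases <- make_cases(
    make_case(2, 480, 780, "A"),  # suitable 08:15-12:45 (bound 270 min)
    make_case(1, 660, 780, "B"),  # suitable 11:15-12:45 given a long bound
    make_case(3, 480, 520, "C")   # suitable 08:15-08:35
  )
  bounds <- make_bounds(c("A", "B", "C"), bound_min = c(285, 240, 240))
  res <- classify_cases(cases, bounds, lunch)
  r <- res[res$code == "A", ]
  expect_true(r$single)
  expect_true(r$two_best)
  expect_false(r$two_least)
  expect_false(r$three)
})

test_that("feasibility flags are nested and monotone in window and duration", {
  wide <- break_policy(30, window_start = "11:00", window_end = "13:00")
  anytime <- break_policy(30)
  short <- break_policy(15, window_start = "11:15", window_end = "12:45")
  withr::with_seed(202, {
    for (i in 1:60) {
      sc <- random_small_schedule()
      res <- lapply(list(lunch, wide, anytime, short), function(p) {
        implementation_flags(sc$cases, sc$bounds, p)
      })
      for (r in res) {
        expect_true(all(!r$three | r$two_least))
        expect_true(all(!r$two_least | r$two_best))
        expect_true(all(!r$two_best | r$single))
      }
      flag_cols <- c("single", "two_best", "two_least", "three")
      # widening the start window can only help, as can removing it
      expect_true(all(res[[1]][flag_cols] <= res[[2]][flag_cols]))
      expect_true(all(res[[2]][flag_cols] <= res[[3]][flag_cols]))
      # a shorter break can only help
      expect_true(all(res[[1]][flag_cols] <= res[[4]][flag_cols]))
    }
  })
})

test_that("interval arithmetic agrees exactly with the minute-grid oracle", {
  withr::with_seed(303, {
    for (i in 1:200) {
      sc <- random_small_schedule()
      pol <- random_policy()
      got <- implementation_flags(sc$cases, sc$bounds, pol)
      want <- dplyr::arrange(oracle_classify(sc$cases, sc$bounds, pol),
                             case_id)
      expect_equal(got, want)
    }
  })
})

test_that("exclusions and denominators partition the future table", {
  st <- generate_study(seed = 5, hist_days = 15, future_days = 3)
  bounds <- lower_prediction_bound(fit_procedure_stats(st$historical))
  res <- classify_cases(st$future, bounds, lunch)
  expect_equal(nrow(res), nrow(st$future))
  # every case is either classified or carries an exclusion reason
  expect_true(all(xor(res$usable, !is.na(res$excluded_reason))))
  expect_true(all(is.na(res$single[!res$usable])))
  expect_true(all(!is.na(res$single[res$usable])))
  # windowed denominator: only usable cases whose interval can meet the window
  expect_true(all(res$usable[res$in_denominator]))
  anytime <- classify_cases(st$future, bounds, break_policy(30))
  expect_equal(anytime$in_denominator, anytime$usable)
  expect_true(sum(anytime$in_denominator) >= sum(res$in_denominator))
})
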