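# Break-feasibility interval calculus. All intervals are numeric minutes from
# midnight of the case's own date; endpoints are snapped to 1e-9 min so that
# minute-resolved schedules compare exactly against integer arithmetic.

#' Period of a case suitable for a break
#'
#' The suitable interval of a case starts at the end of the lead-in
#' (`surgery_start + lead_in_min`) and ends at the earlier of the predicted
#' safe end (`surgery_start + bound_hours`, the lower prediction bound) and
#' the actual case end — the case may finish sooner than predicted. An
#' interval with `end <= start` is empty: the case is predicted too brief for
#' any relief.
#'
#' @param cases A case tibble carrying `bound_hours` and `usable` columns
#'   (see [case_bounds()]). All rows must have a usable bound; filter first.
#' @param policy A [break_policy()].
#' @return `cases` with `int_start`, `int_end` (minutes from midnight of
#'   `date`) and `int_empty` columns.
#' @examples
#' cases <- tibble::tibble(
#'   facility = "f", room = 1L, code = "X", service = "s",
#'   date = as.Date("2020-01-06"),
#'   surgery_start = as.POSIXct("2020-01-06 08:00", tz = "UTC"),
#'   surgery_end = as.POSIXct("2020-01-06 10:30", tz = "UTC"),
#'   bound_hours = 2, usable = TRUE)
#' suitable_interval(cases, break_policy(30))[, c("int_start", "int_end")] / 60
#' @export
suitable_interval <- function(cases, policy) {
  if (!all(cases$usable)) {
    stop("all cases must have a usable prediction bound; filter on `usable`",
         call. = FALSE)
  }
  s0 <- posix_to_date_min(cases$surgery_start, cases$date)
  e_act <- posix_to_date_min(cases$surgery_end, cases$date)
  e_pred <- s0 + cases$bound_hours * 60 -
    if (policy$bound_end_rule == "subtract_lead_in") policy$lead_in_min else 0
  int_start <- snap_min(s0 + policy$lead_in_min)
  int_end <- snap_min(pmin(e_pred, e_act))
  dplyr::mutate(cases, int_start = int_start, int_end = int_end,
                int_empty = int_end <= int_start)
}

#' Cyclically adjacent rooms
#'
#' The two neighbors of a room are the previous and next room in the sorted
#' cyclic order of rooms present that day, wrapping around the suite. With a
#' single room present, both neighbors are the room itself; with two, both
#' neighbors are the other room.
#'
#' @param room A room number present in `rooms_present`.
#' @param rooms_present Integer vector of rooms in use (any order).
#' @return Named integer vector `c(prev = , next = )`.
#' @examples
#' adjacent_rooms(1, 1:10)  # c(prev = 10, next = 2)
#' @export
adjacent_rooms <- function(room, rooms_present) {
  rooms <- sort(unique(as.integer(rooms_present)))
  i <- match(as.integer(room), rooms)
  if (is.na(i)) stop("room ", room, " is not among the rooms present",
                     call. = FALSE)
  k <- length(rooms)
  c(prev = rooms[(i - 2) %% k + 1], `next` = rooms[i %% k + 1])
}

#' Maximum overlap of a case's suitable interval with an adjacent room
#'
#' Intersects the index case's suitable interval with each suitable interval
#' in the neighboring room and returns the single longest intersection (a
#' break is contiguous, so disjoint pieces are never united). When the
#' neighbor room has no case, or no neighbor interval intersects the index
#' interval, the full index interval is returned: the supervisor effectively
#' has one ongoing case, the best chance. Ties in length go to the earliest
#' intersection.
#'
#' @param index Numeric length-2 vector `c(start, end)` in minutes.
#' @param neighbors A data frame with `int_start`, `int_end` columns (one row
#'   per neighbor case), or `NULL`.
#' @return Numeric length-2 `c(start, end)`.
#' @examples
#' overlap_with_room(c(495, 720),
#'                   tibble::tibble(int_start = c(510, 600),
#'                                  int_end = c(540, 690)))
#' @export
overlap_with_room <- function(index, neighbors = NULL) {
  stopifnot(length(index) == 2, index[1] < index[2])
  if (is.null(neighbors) || nrow(neighbors) == 0) return(unname(index))
  lo <- pmax(index[1], neighbors$int_start)
  hi <- pmin(index[2], neighbors$int_end)
  len <- hi - lo
  keep <- len > 0
  if (!any(keep)) return(unname(index))
  best <- which(keep)[order(-len[keep], lo[keep])][1]
  c(lo[best], hi[best])
}

#' Can a break fit in an interval?
#'
#' A break of `duration_min` minutes fits when some start time `s` inside the
#' policy's clock window satisfies `s >= start` and `s + duration <= end`;
#' the break must *start* in the window but may end after it. The earliest
#' admissible start is `max(start, window_start)`, so feasibility reduces to
#' that start being no later than `window_end` and leaving room for the full
#' duration. With an unrestricted policy the test is simply
#' `end - start >= duration`.
#'
#' @param start,end Numeric vectors, minutes from midnight. An element with
#'   `end <= start` is an empty interval and infeasible.
#' @param policy A [break_policy()].
#' @return Logical vector.
#' @examples
#' pol <- break_policy(30, window_start = "11:15", window_end = "12:45")
#' break_feasible(495, 720, pol)   # interval 08:15-12:00: break 11:15-11:45
#' break_feasible(770, 840, pol)   # 12:50-14:00: start after window end
#' @export
break_feasible <- function(start, end, policy) {
  empty <- end <= start
  if (!policy$restricted) {
    return(!empty & (end - start >= policy$duration_min))
  }
  s <- pmax(start, policy$window_start)
  !empty & s <= policy$window_end & s + policy$duration_min <= end
}

# Windowed-denominator rule: a case enters a windowed analysis only when a
# break starting inside the window could possibly overlap its suitable
# interval. Unrestricted analyses count every case with a computable bound.
in_denominator <- function(start, end, policy) {
  nonempty <- end > start
  if (!policy$restricted) return(rep(TRUE, length(start)))
  nonempty & start <= policy$window_end & end >= policy$window_start
}

#' Classify break feasibility of every future case
#'
#' For each future case with a usable prediction bound, decides whether the
#' supervising anesthesiologist could give the break while covering one, two,
#' or three rooms:
#' * `single` — the break fits in the case's own suitable interval;
#' * for each of the two cyclically adjacent rooms, the break is tested in
#'   the maximum overlap of the index interval with that room
#'   ([overlap_with_room()]); `two_best` is the OR of the two room results
#'   and `two_least` the AND;
#' * `three` — the break is tested in the intersection of the index interval
#'   with both rooms' maximum-overlap intervals (an empty neighbor room
#'   contributes no constraint).
#'
#' The four flags are nested by construction: `three` implies `two_least`
#' implies `two_best` implies `single`. Adjacency and overlap are computed
#' within one facility-date. Cases without a usable bound get `NA` flags and
#' an `excluded_reason`; neighbor cases without a usable bound contribute no
#' suitable interval. `in_denominator` marks cases that count toward the
#' policy's denominator (all bound-bearing cases for an unrestricted policy;
#' for a windowed policy, cases whose suitable interval could meet a break
#' started in the window).
#'
#' @param future A future-period case tibble.
#' @param bounds Per-code bounds from [lower_prediction_bound()].
#' @param policy A [break_policy()].
#' @return A tibble of class `break_classification`, one row per future case:
#'   identifiers, `weekday`, `hours`, `usable`, `excluded_reason`,
#'   `int_start`, `int_end`, `in_denominator`, and the logical flags
#'   `single`, `two_best`, `two_least`, `three`. The policy is attached as
#'   attribute `"policy"`.
#' @examples
#' st <- generate_study(1, hist_days = 20, future_days = 2)
#' b <- lower_prediction_bound(fit_procedure_stats(st$historical))
#' cls <- classify_cases(st$future, b, default_policies()$lunch)
#' table(cls$single, useNA = "ifany")
#' @export
classify_cases <- function(future, bounds, policy) {
  cases <- case_bounds(future, bounds)
  u <- dplyr::filter(cases, .data$usable) |>
    suitable_interval(policy)

  # cyclic adjacency from every room in use that day (bound or not)
  adj <- cases |>
    dplyr::distinct(.data$facility, .data$date, .data$room) |>
    dplyr::group_by(.data$facility, .data$date) |>
    dplyr::arrange(.data$room, .by_group = TRUE) |>
    dplyr::mutate(
      nb_prev = .data$room[(dplyr::row_number() - 2) %% dplyr::n() + 1],
      nb_next = .data$room[dplyr::row_number() %% dplyr::n() + 1]
    ) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(c("nb_prev", "nb_next"), names_to = "side",
                        values_to = "nb_room")

  idx <- u |>
    dplyr::filter(!.data$int_empty) |>
    dplyr::select("case_id", "facility", "date", "room",
                  "int_start", "int_end")
  nb <- u |>
    dplyr::filter(!.data$int_empty) |>
    dplyr::select("facility", "date", nb_room = "room",
                  nb_id = "case_id", nb_start = "int_start",
                  nb_end = "int_end")

  sides <- idx |>
    dplyr::inner_join(adj, by = c("facility", "date", "room"),
                      relationship = "many-to-many") |>
    dplyr::left_join(nb, by = c("facility", "date", "nb_room"),
                     relationship = "many-to-many") |>
    dplyr::mutate(
      ov_start = pmax(.data$int_start, .data$nb_start),
      ov_end = pmin(.data$int_end, .data$nb_end),
      ov_len = .data$ov_end - .data$ov_start,
      # a case is never its own neighbor constraint
      hit = !is.na(.data$ov_len) & .data$ov_len > 0 &
        .data$nb_id != .data$case_id
    ) |>
    dplyr::group_by(.data$case_id, .data$side) |>
    dplyr::arrange(dplyr::desc(.data$hit), dplyr::desc(.data$ov_len),
                   .data$ov_start, .by_group = TRUE) |>
    dplyr::summarise(
      s_start = ifelse(.data$hit[1], .data$ov_start[1], .data$int_start[1]),
      s_end = ifelse(.data$hit[1], .data$ov_end[1], .data$int_end[1]),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "side",
                       values_from = c("s_start", "s_end"))
  for (nm in c("s_start_nb_prev", "s_end_nb_prev", "s_start_nb_next",
               "s_end_nb_next")) {
    if (!nm %in% names(sides)) sides[[nm]] <- numeric(0)
  }

  flags <- idx |>
    dplyr::left_join(sides, by = "case_id") |>
    dplyr::mutate(
      single = break_feasible(.data$int_start, .data$int_end, policy),
      f_prev = break_feasible(.data$s_start_nb_prev, .data$s_end_nb_prev,
                              policy),
      f_next = break_feasible(.data$s_start_nb_next, .data$s_end_nb_next,
                              policy),
      two_best = .data$f_prev | .data$f_next,
      two_least = .data$f_prev & .data$f_next,
      three = break_feasible(
        pmax(.data$s_start_nb_prev, .data$s_start_nb_next),
        pmin(.data$s_end_nb_prev, .data$s_end_nb_next), policy
      )
    ) |>
    dplyr::select("case_id", "single", "two_best", "two_least", "three")

  out <- cases |>
    dplyr::left_join(
      dplyr::select(u, "case_id", "int_start", "int_end", "int_empty"),
      by = "case_id"
    ) |>
    dplyr::left_join(flags, by = "case_id") |>
    dplyr::mutate(
      weekday = factor(format(.data$date, "%a"),
                       levels = c("Mon", "Tue", "Wed", "Thu", "Fri",
                                  "Sat", "Sun")),
      dplyr::across(c("single", "two_best", "two_least", "three"),
                    ~ dplyr::if_else(.data$usable, dplyr::coalesce(.x, FALSE),
                                     NA)),
      in_denominator = .data$usable &
        in_denominator(dplyr::coalesce(.data$int_start, 0),
                       dplyr::coalesce(.data$int_end, -1), policy)
    ) |>
    dplyr::select("case_id", "facility", "date", "weekday", "room", "code",
                  "service", "hours", "bound_hours", "usable",
                  "excluded_reason", "int_start", "int_end", "int_empty",
                  "in_denominator", "single", "two_best", "two_least",
                  "three")
  attr(out, "policy") <- policy
  class(out) <- c("break_classification", class(out))
  out
}
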