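#' Define a break policy
#'
#' A break policy describes the relief being planned: how long the break is,
#' how long after the start of surgery relief may first begin (the lead-in,
#' covering induction completion, positioning, and initial documentation), the
#' clock window within which the break must *start* (or no window at all, for
#' a break anytime in the workday), and the lower-tail risk of the surgical
#' time prediction bound used to decide when a case is safely long enough.
#'
#' The break must start inside `[window_start, window_end]` but may end after
#' `window_end`. With `bound_end_rule = "full_bound"` (the default) the period
#' suitable for a break in a case runs from `surgery_start + lead_in_min` to
#' the earlier of `surgery_start + bound` and the actual case end;
#' `"subtract_lead_in"` additionally subtracts the lead-in from the predicted
#' end, the stricter alternative reading.
#'
#' @param duration_min Break length in minutes (> 0), e.g. 30 for a lunch
#'   break or 15 for a mid-morning break.
#' @param lead_in_min Minutes after the start of surgery before relief can
#'   begin. Default 15.
#' @param window_start,window_end Clock times (`"HH:MM"` strings or minutes
#'   from midnight) bounding the break start, or both `NULL` for a break
#'   anytime in the workday.
#' @param risk Lower-tail risk of the prediction bound (default 0.05 for a 5%
#'   lower bound).
#' @param label Short label used in summaries; a default is built from the
#'   window.
#' @param bound_end_rule `"full_bound"` or `"subtract_lead_in"`; see Details.
#' @return An object of class `break_policy`.
#' @examples
#' break_policy(30, window_start = "11:15", window_end = "12:45")
#' break_policy(15) # 15-minute break anytime in the workday
#' @export
break_policy <- function(duration_min, lead_in_min = 15,
                         window_start = NULL, window_end = NULL,
                         risk = 0.05, label = NULL,
                         bound_end_rule = c("full_bound", "subtract_lead_in")) {
  bound_end_rule <- match.arg(bound_end_rule)
  stopifnot(is.numeric(duration_min), length(duration_min) == 1,
            duration_min > 0, is.numeric(lead_in_min), lead_in_min >= 0,
            is.numeric(risk), risk > 0, risk < 1)
  if (xor(is.null(window_start), is.null(window_end))) {
    stop("provide both `window_start` and `window_end`, or neither",
         call. = FALSE)
  }
  ws <- hm_to_min(window_start)
  we <- hm_to_min(window_end)
  if (!is.null(ws) && ws > we) {
    stop("`window_start` must not be after `window_end`", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (is.null(ws)) {
      sprintf("%g-min break, anytime", duration_min)
    } else {
      sprintf("%g-min break, start %s-%s", duration_min,
              min_to_hm(ws), min_to_hm(we))
    }
  }
  structure(
    list(duration_min = duration_min, lead_in_min = lead_in_min,
         window_start = ws, window_end = we, restricted = !is.null(ws),
         risk = risk, label = label, bound_end_rule = bound_end_rule),
    class = "break_policy"
  )
}

#' @export
print.break_policy <- function(x, ...) {
  cat("<break_policy> ", x$label, "\n", sep = "")
  cat("  lead-in ", x$lead_in_min, " min; prediction-bound risk ",
      x$risk, "; end rule ", x$bound_end_rule, "\n", sep = "")
  invisible(x)
}

#' Standard break policies
#'
#' The policy set used throughout the package: a 30-minute lunch break
#' starting 11:15-12:45, a 15-minute mid-morning break starting 9:00-10:30,
#' anytime-in-the-workday variants of both, and the sensitivity variant with
#' the lunch window widened from 1.5 to 2.0 hours (11:00-13:00).
#'
#' @param risk Prediction-bound risk shared by all policies (default 0.05).
#' @return A named list of [break_policy()] objects.
#' @examples
#' names(default_policies())
#' @export
default_policies <- function(risk = 0.05) {
  list(
    lunch            = break_policy(30, window_start = "11:15",
                                    window_end = "12:45", risk = risk),
    lunch_anytime    = break_policy(30, risk = risk),
    morning          = break_policy(15, window_start = "09:00",
                                    window_end = "10:30", risk = risk),
    morning_anytime  = break_policy(15, risk = risk),
    lunch_wide       = break_policy(30, window_start = "11:00",
                                    window_end = "13:00", risk = risk)
  )
}
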