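# Fixture builders: all tables are constructed in code at test time.

MONDAY <- as.Date("2020-01-06")

# one case row from clock minutes on a given date
make_case <- function(room, start_min, end_min, code, date = MONDAY,
                      facility = "fac", service = "svc") {
  tibble::tibble(
    facility = facility, room = as.integer(room), code = code,
    service = service, date = date,
    surgery_start = as.POSIXct(as.character(date), tz = "UTC") +
      start_min * 60,
    surgery_end = as.POSIXct(as.character(date), tz = "UTC") + end_min * 60
  )
}

# stack several make_case() rows
make_cases <- function(...) dplyr::bind_rows(...)

# per-code bounds table with hand-set bounds in minutes
make_bounds <- function(codes, bound_min, n = 99L) {
  tibble::tibble(code = codes, n = n, bound_hours = bound_min / 60,
                 usable = TRUE)
}

# one-row archetype with a custom catalog (used for targeted simulations)
make_archetype <- function(catalog, facility = "test", n_rooms = 1L,
                           workday_start = "07:45", workday_end = "17:00",
                           turnover_min = 30) {
  tibble::tibble(facility = facility, n_rooms = as.integer(n_rooms),
                 workday_start = workday_start, workday_end = workday_end,
                 turnover_min = turnover_min, catalog = list(catalog))
}

# a random one-day schedule on integer minutes with hand-set integer bounds:
# <= max_rooms rooms, <= max_cases cases per room, sequential within room
random_small_schedule <- function(max_rooms = 4, max_cases = 3) {
  n_rooms <- sample(1:max_rooms, 1)
  rooms <- sort(sample(1:10, n_rooms))
  cases <- list()
  k <- 0
  for (r in rooms) {
    n_cases <- sample(0:max_cases, 1)
    t <- 465 + sample(0:120, 1)
    for (j in seq_len(n_cases)) {
      dur <- sample(10:300, 1)
      k <- k + 1
      cases[[k]] <- make_case(r, t, t + dur, code = sprintf("C%03d", k))
      t <- t + dur + sample(20:90, 1)
    }
  }
  if (k == 0) {
    k <- 1
    cases[[1]] <- make_case(rooms[1], 480, 600, "C001")
  }
  cases <- dplyr::bind_rows(cases)
  bounds <- make_bounds(cases$code, bound_min = sample(5:300, nrow(cases),
                                                       replace = TRUE))
  list(cases = cases, bounds = bounds)
}

random_policy <- function() {
  if (runif(1) < 0.4) {
    break_policy(sample(c(15, 30), 1))
  } else {
    ws <- sample(480:800, 1)
    break_policy(sample(c(15, 30), 1), window_start = ws,
                 window_end = ws + sample(c(60, 90, 120), 1))
  }
}
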