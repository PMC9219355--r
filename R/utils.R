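# Internal helpers shared across modules. All break-time arithmetic is done in
# minutes from midnight of the case's own calendar date (so a case running past
# midnight simply has an end > 1440).

# "HH:MM" -> minutes from midnight
hm_to_min <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid clock time(s): ", paste(x[bad], collapse = ", "),
         " (expected HH:MM)", call. = FALSE)
  }
  vapply(m, function(p) as.numeric(p[2]) * 60 + as.numeric(p[3]), 1)
}

min_to_hm <- function(x) {
  sprintf("%02d:%02d", as.integer(x %/% 60), as.integer(round(x %% 60)))
}

# round half away from zero (table display convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# first n weekdays (Mon-Fri) on/after `start`
weekday_seq <- function(start, n) {
  start <- as.Date(start)
  if (n == 0) return(start[0])
  cand <- seq(start, by = "day", length.out = ceiling(n / 5) * 7 + 7)
  cand <- cand[!format(cand, "%u") %in% c("6", "7")]
  cand[seq_len(n)]
}

# POSIXct (UTC) at `minutes` past midnight of `date`
date_min_to_posix <- function(date, minutes) {
  as.POSIXct(as.character(date), tz = "UTC") + minutes * 60
}

# minutes from midnight of `date` to timestamp `ts`
posix_to_date_min <- function(ts, date) {
  as.numeric(ts - as.POSIXct(as.character(date), tz = "UTC"), units = "mins")
}

# snap away double round-off so minute-resolved schedules compare exactly
snap_min <- function(x) round(x, 9)

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  x[which(cw >= 0.5)[1]]
}

surgical_hours <- function(cases) {
  as.numeric(cases$surgery_end - cases$surgery_start, units = "hours")
}

format_pct_cell <- function(pct, lo, hi) {
  ifelse(is.na(pct), "", sprintf("%.1f (%.1f, %.1f)",
                                 round_half_up(pct), round_half_up(lo),
                                 round_half_up(hi)))
}
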