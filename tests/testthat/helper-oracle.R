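# Independent minute-grid brute force for break feasibility. Works only on
# schedules whose times and bounds are whole minutes; feasibility of a break
# inside integer-endpoint intervals is then decided by enumerating every
# integer start minute, and interval overlaps by intersecting minute sets.

# minutes covered by the half-open interval [lo, hi)
minute_set <- function(lo, hi) if (hi > lo) seq(lo, hi - 1) else integer(0)

# is there an integer start s with [s, s+D) inside [lo, hi) and s in window?
oracle_fits <- function(lo, hi, policy) {
  D <- policy$duration_min
  starts <- if (policy$restricted) {
    seq(policy$window_start, policy$window_end)
  } else if (hi - D >= lo) {
    seq(lo, hi - D)
  } else {
    integer(0)
  }
  any(starts >= lo & starts + D <= hi)
}

# brute-force flags for every case of a one-day schedule
oracle_classify <- function(cases, bounds, policy) {
  df <- dplyr::left_join(add_case_ids(cases), bounds, by = "code")
  mid <- as.POSIXct(as.character(df$date), tz = "UTC")
  # schedules handed to the oracle are integer minutes by construction, but
  # POSIXct arithmetic leaves ~1e-13 fuzz; round so minute sets are integers
  df$lo <- round(as.numeric(df$surgery_start - mid, units = "mins") +
                   policy$lead_in_min)
  df$hi <- round(pmin(
    as.numeric(df$surgery_start - mid, units = "mins") +
      round(df$bound_hours * 60),
    as.numeric(df$surgery_end - mid, units = "mins")
  ))
  rooms <- sort(unique(df$room))
  k <- length(rooms)

  side_interval <- function(i, nb_room) {
    index_set <- minute_set(df$lo[i], df$hi[i])
    nb <- which(df$room == nb_room & seq_len(nrow(df)) != i &
                  df$usable & df$hi > df$lo)
    best_len <- 0
    best_lo <- NA
    for (j in nb) {
      common <- intersect(index_set, minute_set(df$lo[j], df$hi[j]))
      if (length(common) > best_len ||
          (length(common) == best_len && length(common) > 0 &&
           min(common) < best_lo)) {
        best_len <- length(common)
        best_lo <- min(common)
      }
    }
    if (best_len == 0) c(df$lo[i], df$hi[i]) else c(best_lo, best_lo + best_len)
  }

  out <- lapply(seq_len(nrow(df)), function(i) {
    if (!df$usable[i] || df$hi[i] <= df$lo[i]) {
      return(tibble::tibble(case_id = df$case_id[i], single = FALSE,
                            two_best = FALSE, two_least = FALSE,
                            three = FALSE))
    }
    pos <- match(df$room[i], rooms)
    nb_prev <- rooms[(pos - 2) %% k + 1]
    nb_next <- rooms[pos %% k + 1]
    iv_prev <- side_interval(i, nb_prev)
    iv_next <- side_interval(i, nb_next)
    f_prev <- oracle_fits(iv_prev[1], iv_prev[2], policy)
    f_next <- oracle_fits(iv_next[1], iv_next[2], policy)
    tibble::tibble(
      case_id = df$case_id[i],
      single = oracle_fits(df$lo[i], df$hi[i], policy),
      two_best = f_prev | f_next,
      two_least = f_prev & f_next,
      three = oracle_fits(max(iv_prev[1], iv_next[1]),
                          min(iv_prev[2], iv_next[2]), policy)
    )
  })
  dplyr::bind_rows(out)
}

# flags from classify_cases() aligned for comparison with the oracle
implementation_flags <- function(cases, bounds, policy) {
  res <- classify_cases(cases, bounds, policy)
  attr(res, "policy") <- NULL
  tibble::as_tibble(res) |>
    dplyr::transmute(case_id,
                     single = isTRUE_vec(single), two_best = isTRUE_vec(two_best),
                     two_least = isTRUE_vec(two_least), three = isTRUE_vec(three)) |>
    dplyr::arrange(case_id)
}

isTRUE_vec <- function(x) !is.na(x) & x
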