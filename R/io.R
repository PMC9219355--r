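# Case-table CSV schema: one row per case, header exactly
#   facility,room,code,service,date,surgery_start,surgery_end
# with ISO-8601 minute-resolution timestamps (YYYY-MM-DDTHH:MM).

case_csv_columns <- c("facility", "room", "code", "service", "date",
                      "surgery_start", "surgery_end")

#' Write a case table to CSV
#'
#' @param cases A case tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_case_table <- function(cases, path) {
  out <- tibble::tibble(
    facility = as.character(cases$facility),
    room = as.integer(cases$room),
    code = as.character(cases$code),
    service = as.character(cases$service),
    date = format(cases$date, "%Y-%m-%d"),
    surgery_start = format(cases$surgery_start, "%Y-%m-%dT%H:%M",
                           tz = "UTC"),
    surgery_end = format(cases$surgery_end, "%Y-%m-%dT%H:%M", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a case table CSV
#'
#' Enforces the schema (header, parseable dates/timestamps, positive integer
#' room, `surgery_end` after `surgery_start`). Violations are rejected with
#' the 1-based file line numbers of the offending rows (the header is line
#' 1).
#'
#' @param path CSV file path.
#' @return A case tibble.
#' @export
read_case_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (!identical(names(raw), case_csv_columns)) {
    stop("malformed case CSV header in ", path, ": expected ",
         paste(case_csv_columns, collapse = ","), call. = FALSE)
  }
  raw$room <- suppressWarnings(as.numeric(raw$room))
  line <- seq_len(nrow(raw)) + 1L
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  start <- as.POSIXct(raw$surgery_start, format = "%Y-%m-%dT%H:%M",
                      tz = "UTC")
  end <- as.POSIXct(raw$surgery_end, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  bad <- list(
    "unparseable date" = is.na(date),
    "unparseable surgery_start" = is.na(start),
    "unparseable surgery_end" = is.na(end),
    "room must be a positive integer" =
      is.na(raw$room) | raw$room < 1 | raw$room != floor(raw$room),
    "surgery_end not after surgery_start" =
      !is.na(start) & !is.na(end) & end <= start
  )
  msgs <- unlist(lapply(names(bad), function(m) {
    ln <- line[bad[[m]]]
    if (length(ln) == 0) return(character(0))
    sprintf("line %s: %s", paste(head(ln, 5), collapse = ", line "), m)
  }))
  if (length(msgs) > 0) {
    stop("invalid rows in ", path, ":\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  tibble::tibble(
    facility = raw$facility, room = as.integer(raw$room), code = raw$code,
    service = raw$service, date = date, surgery_start = start,
    surgery_end = end
  )
}

#' Default run configuration
#'
#' The full set of pipeline parameters with their defaults: the seed, the
#' historical and future weekday counts (three years and one year of
#' weekdays), the policies analysed, and the output directory.
#'
#' @return A named list.
#' @export
default_run_config <- function() {
  list(seed = 1L, hist_days = 756L, future_days = 252L,
       risk = 0.05,
       policies = paste(names(default_policies()), collapse = ","),
       out_dir = "orbreaks-output")
}

#' Read a plain-text key=value run configuration
#'
#' Unknown keys are rejected; missing keys keep their defaults. Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return A named list as in [default_run_config()].
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln, call. = FALSE)
    key <- kv[2]
    if (!key %in% names(cfg)) stop("unknown config key: ", key,
                                   call. = FALSE)
    val <- kv[3]
    cfg[[key]] <- if (is.numeric(cfg[[key]])) as.numeric(val) else val
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$hist_days <- as.integer(cfg$hist_days)
  cfg$future_days <- as.integer(cfg$future_days)
  cfg
}

format_run_config <- function(cfg) {
  paste0(names(cfg), " = ", unlist(cfg))
}

config_policies <- function(cfg) {
  all <- default_policies(risk = cfg$risk)
  want <- strsplit(cfg$policies, ",")[[1]]
  unknown <- setdiff(want, names(all))
  if (length(unknown) > 0) {
    stop("unknown policy name(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(all), collapse = ", "), call. = FALSE)
  }
  all[want]
}
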