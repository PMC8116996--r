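#' Clinic work schedule
#'
#' A work schedule is a tibble of scheduled shifts by weekday, with times
#' as minutes from midnight. The default mirrors a typical outpatient
#' schedule: Monday-Friday clinics 08:30-12:30 and 13:30-17:30, with
#' weekends unscheduled. A weekday with at least one shift is a workday.
#'
#' @param shifts list of `c(start, end)` clock times (`"HH:MM"` strings or
#'   minutes from midnight) applied to every working weekday
#' @param weekdays integer weekdays the shifts apply to (1 = Monday ...
#'   7 = Sunday)
#' @return tibble with columns `wday`, `shift_start`, `shift_end` (minutes
#'   from midnight), class `work_schedule`
#' @examples
#' work_schedule()
#' work_schedule(shifts = list(c("09:00", "17:00")))
#' @export
work_schedule <- function(shifts = list(c("08:30", "12:30"), c("13:30", "17:30")),
                          weekdays = 1:5) {
  rows <- purrr::map(shifts, function(s) {
    st <- .hhmm_to_min(s[[1]]); en <- .hhmm_to_min(s[[2]])
    if (en <= st) abort("shift end must be after shift start")
    tibble(shift_start = st, shift_end = en)
  }) |> list_rbind()
  out <- tidyr::expand_grid(wday = as.integer(weekdays), rows) |>
    arrange(.data$wday, .data$shift_start)
  # shifts must not overlap within a weekday
  bad <- out |>
    group_by(.data$wday) |>
    filter(dplyr::lag(.data$shift_end, default = -Inf) > .data$shift_start) |>
    nrow()
  if (bad > 0) abort("shifts overlap within a weekday")
  class(out) <- c("work_schedule", class(out))
  out
}

#' @export
print.work_schedule <- function(x, ...) {
  cat("<work_schedule>\n")
  for (w in sort(unique(x$wday))) {
    sh <- x[x$wday == w, ]
    cat(sprintf("  %s: %s\n",
                c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[w],
                paste(.min_to_hhmm(sh$shift_start), "-",
                      .min_to_hhmm(sh$shift_end), collapse = ", ")))
  }
  invisible(x)
}

#' Read a work schedule from a YAML or JSON file
#'
#' The file holds a list of shifts (each with `start`/`end` clock strings)
#' and optionally `weekdays`.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`)
#' @return a [work_schedule()]
#' @export
read_schedule <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  shifts <- purrr::map(spec$shifts, function(s) c(s$start, s$end))
  weekdays <- spec$weekdays %||% 1:5
  work_schedule(shifts = shifts, weekdays = weekdays)
}

#' Is a date a scheduled workday?
#'
#' @param date `Date` vector
#' @param schedule a [work_schedule()]
#' @return logical vector
#' @export
is_workday <- function(date, schedule = work_schedule()) {
  .wday_num(date) %in% unique(schedule$wday)
}

# shifts (minutes from midnight) scheduled on a given date; zero-row tibble
# on non-workdays
.shifts_on <- function(date, schedule) {
  schedule[schedule$wday == .wday_num(date), c("shift_start", "shift_end")]
}
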