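#' Sessionize EHR access-log events into attributed time intervals
#'
#' Raw audit logs record discrete interactions, not durations. Time is
#' attributed by last-event-carried-forward: each event opens an interval
#' that ends at the next event for the same physician or after
#' `idle_cutoff` minutes, whichever comes first. The final event of a
#' stream is attributed exactly `idle_cutoff` minutes. Intervals inherit
#' the opening event's activity category and message type and are
#' half-open `[start, end)`.
#'
#' @param events tibble of log events with columns `timestamp` (POSIXct),
#'   `physician_id`, `category` (`"INBOX"` or `"OTHER_EHR"`),
#'   `message_type` (`"PATIENT"`, `"RESULT"`, `"REQUEST"`, `"ADMIN"`, or
#'   `"NONE"` for non-inbox work), `window_id`, `is_task_completion`
#' @param idle_cutoff idle cutoff in minutes (default 5); inactivity longer
#'   than this is not attributed to the preceding event
#' @return tibble of intervals: `physician_id`, `date`, `start`, `end`,
#'   `minutes`, `category`, `message_type`
#' @examples
#' ev <- tibble::tibble(
#'   timestamp = as.POSIXct("2023-03-06 09:00:00", tz = "UTC") + c(0, 120),
#'   physician_id = "p1", category = "INBOX", message_type = "RESULT",
#'   window_id = "w1", is_task_completion = FALSE
#' )
#' sessionize(ev)  # 2 minutes, then the 5-minute cutoff
#' @export
sessionize <- function(events, idle_cutoff = 5) {
  if (nrow(events) == 0) {
    return(tibble(physician_id = character(), date = as.Date(character()),
                  start = .as_instant(character()), end = .as_instant(character()),
                  minutes = numeric(), category = character(),
                  message_type = character()))
  }
  stopifnot(idle_cutoff > 0)
  .validate_events(events)
  events |>
    group_by(.data$physician_id) |>
    mutate(gap = as.numeric(difftime(dplyr::lead(.data$timestamp),
                                     .data$timestamp, units = "mins")),
           minutes = pmin(coalesce(.data$gap, Inf), idle_cutoff)) |>
    ungroup() |>
    transmute(.data$physician_id,
              date = .date_of(.data$timestamp),
              start = .data$timestamp,
              end = .data$timestamp + .data$minutes * 60,
              .data$minutes, .data$category, .data$message_type)
}

.validate_events <- function(events) {
  need <- c("timestamp", "physician_id", "category", "message_type",
            "window_id", "is_task_completion")
  missing <- setdiff(need, names(events))
  if (length(missing) > 0) {
    abort(paste("events missing columns:", paste(missing, collapse = ", ")))
  }
  unsorted <- events |>
    group_by(.data$physician_id) |>
    summarise(bad = any(diff(as.numeric(.data$timestamp)) < 0)) |>
    filter(.data$bad)
  if (nrow(unsorted) > 0) {
    abort(paste("events not sorted by timestamp for physician(s):",
                paste(unsorted$physician_id, collapse = ", ")))
  }
  if (!all(events$category %in% c("INBOX", "OTHER_EHR"))) {
    abort("category must be INBOX or OTHER_EHR")
  }
  bad_type <- (events$category == "OTHER_EHR") != (events$message_type == "NONE")
  if (any(bad_type)) {
    abort("message_type must be NONE exactly when category is OTHER_EHR")
  }
  invisible(events)
}

#' Split attributed intervals across anchored hour bins
#'
#' Intervals are cut at hour-bin boundaries so that every minute lands in
#' exactly one bin; total minutes are conserved. Bins are half-open hours
#' anchored `bin_anchor` minutes past the hour (default 30, giving
#' 08:30-09:30 style bins aligned to an 08:30 shift start).
#'
#' @param intervals output of [sessionize()] (or any tibble with
#'   `physician_id`, `start`, `end`, `category`, `message_type`)
#' @param bin_anchor minutes past the hour at which bins start
#' @return tibble of per-physician per-bin minutes by category and message
#'   type: `physician_id`, `bin_start`, `date`, `category`, `message_type`,
#'   `minutes`
#' @export
bin_hourly <- function(intervals, bin_anchor = 30) {
  if (nrow(intervals) == 0) {
    return(tibble(physician_id = character(), bin_start = .as_instant(character()),
                  date = as.Date(character()), category = character(),
                  message_type = character(), minutes = numeric()))
  }
  first_bin <- .bin_start(intervals$start, bin_anchor)
  n_bins <- floor(as.numeric(difftime(intervals$end, first_bin, units = "hours")) - 1e-12) + 1L
  idx <- rep(seq_len(nrow(intervals)), n_bins)
  k <- sequence(n_bins) - 1L
  bin_start <- first_bin[idx] + k * 3600
  piece_start <- pmax(as.numeric(intervals$start[idx]), as.numeric(bin_start))
  piece_end <- pmin(as.numeric(intervals$end[idx]), as.numeric(bin_start) + 3600)
  tibble(physician_id = intervals$physician_id[idx],
         bin_start = bin_start,
         category = intervals$category[idx],
         message_type = intervals$message_type[idx],
         minutes = (piece_end - piece_start) / 60) |>
    filter(.data$minutes > 0) |>
    group_by(.data$physician_id, .data$bin_start, .data$category,
             .data$message_type) |>
    summarise(minutes = sum(.data$minutes), .groups = "drop") |>
    mutate(date = .date_of(.data$bin_start), .after = "bin_start")
}

#' Count window switches and completed tasks per hour bin
#'
#' A window switch is an event whose `window_id` differs from the
#' physician's immediately preceding event; the first event of a
#' physician's stream is not a switch. Task completions are counted from
#' the `is_task_completion` marker.
#'
#' @inheritParams sessionize
#' @inheritParams bin_hourly
#' @return tibble: `physician_id`, `bin_start`, `n_window_switches`,
#'   `n_tasks`
#' @export
count_window_switches <- function(events, bin_anchor = 30) {
  if (nrow(events) == 0) {
    return(tibble(physician_id = character(), bin_start = .as_instant(character()),
                  n_window_switches = integer(), n_tasks = integer()))
  }
  .validate_events(events)
  events |>
    group_by(.data$physician_id) |>
    mutate(switch = .data$window_id != dplyr::lag(.data$window_id,
                                                  default = dplyr::first(.data$window_id))) |>
    ungroup() |>
    mutate(bin_start = .bin_start(.data$timestamp, bin_anchor)) |>
    group_by(.data$physician_id, .data$bin_start) |>
    summarise(n_window_switches = sum(.data$switch),
              n_tasks = sum(.data$is_task_completion), .groups = "drop")
}

#' Hourly EHR usage table
#'
#' One row per physician per hour bin with any EHR activity: minutes in
#' the EHR, minutes in the inbox, inbox minutes by message type, window
#' switches and completed tasks. This is the hourly feature table every
#' downstream stage consumes.
#'
#' @inheritParams sessionize
#' @param idle_cutoff idle cutoff in minutes passed to [sessionize()]
#' @param bin_anchor hour-bin anchor passed to [bin_hourly()]
#' @return tibble with columns `physician_id`, `date`, `bin_start`,
#'   `minutes_ehr`, `minutes_inbox`, `minutes_patient`, `minutes_result`,
#'   `minutes_request`, `minutes_admin`, `n_tasks`, `n_window_switches`
#' @export
hourly_usage <- function(events, idle_cutoff = 5, bin_anchor = 30) {
  ints <- sessionize(events, idle_cutoff)
  binned <- bin_hourly(ints, bin_anchor)
  counts <- count_window_switches(events, bin_anchor)
  type_cols <- c(PATIENT = "minutes_patient", RESULT = "minutes_result",
                 REQUEST = "minutes_request", ADMIN = "minutes_admin")
  wide <- binned |>
    mutate(slot = ifelse(.data$category == "OTHER_EHR", "minutes_other",
                         unname(type_cols[.data$message_type]))) |>
    group_by(.data$physician_id, .data$date, .data$bin_start, .data$slot) |>
    summarise(minutes = sum(.data$minutes), .groups = "drop") |>
    pivot_wider(names_from = "slot", values_from = "minutes", values_fill = 0)
  for (col in c(type_cols, "minutes_other")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide |>
    mutate(minutes_inbox = .data$minutes_patient + .data$minutes_result +
             .data$minutes_request + .data$minutes_admin,
           minutes_ehr = .data$minutes_inbox + .data$minutes_other) |>
    select(-"minutes_other") |>
    left_join(counts, by = c("physician_id", "bin_start")) |>
    mutate(n_window_switches = coalesce(.data$n_window_switches, 0L),
           n_tasks = coalesce(.data$n_tasks, 0L)) |>
    select("physician_id", "date", "bin_start", "minutes_ehr", "minutes_inbox",
           "minutes_patient", "minutes_result", "minutes_request",
           "minutes_admin", "n_tasks", "n_window_switches") |>
    arrange(.data$physician_id, .data$bin_start)
}

#' Window-switching rate per physician-day
#'
#' Switches per minute of EHR use: total window switches divided by total
#' EHR minutes. Days with no EHR time get `NA`.
#'
#' @param hourly output of [hourly_usage()]
#' @return tibble: `physician_id`, `date`, `switch_rate`
#' @export
switching_rate <- function(hourly) {
  hourly |>
    group_by(.data$physician_id, .data$date) |>
    summarise(switches = sum(.data$n_window_switches),
              ehr = sum(.data$minutes_ehr), .groups = "drop") |>
    mutate(switch_rate = ifelse(.data$ehr > 0, .data$switches / .data$ehr,
                                NA_real_)) |>
    select("physician_id", "date", "switch_rate")
}

#' Minutes of inbox work per message handled
#'
#' Messages handled are counted from task-completion markers on inbox
#' events (the logs carry no message identifiers). Days with no completed
#' messages get `NA`.
#'
#' @param hourly output of [hourly_usage()]
#' @return tibble: `physician_id`, `date`, `n_messages`, `time_per_message`
#'   (minutes)
#' @export
time_per_message <- function(hourly) {
  hourly |>
    group_by(.data$physician_id, .data$date) |>
    summarise(inbox = sum(.data$minutes_inbox),
              n_messages = sum(.data$n_tasks), .groups = "drop") |>
    mutate(time_per_message = ifelse(.data$n_messages > 0,
                                     .data$inbox / .data$n_messages, NA_real_)) |>
    select("physician_id", "date", "n_messages", "time_per_message")
}
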