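#' Read EHR access-log events
#'
#' Accepts CSV or JSON-lines with columns `timestamp` (ISO-8601),
#' `physician_id`, `category`, `message_type`, `window_id`,
#' `is_task_completion`. The schema is validated on load: events must be
#' time-sorted within physician, categories limited to INBOX/OTHER_EHR,
#' and `message_type` must be `NONE` exactly for non-inbox events.
#'
#' @param path file path (`.csv`, `.json` or `.jsonl`)
#' @return validated tibble of log events
#' @export
read_log_events <- function(path) {
  raw <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  ev <- as_tibble(raw) |>
    mutate(timestamp = .as_instant(.data$timestamp),
           physician_id = as.character(.data$physician_id),
           is_task_completion = as.logical(.data$is_task_completion)) |>
    arrange(.data$physician_id, .data$timestamp)
  .validate_events(ev)
  ev
}

#' Read wearable stress samples
#'
#' CSV with `physician_id`, `timestamp` (ISO-8601, start of the 3-minute
#' sample window), `score` (0-100 or empty), `activity_flag`.
#'
#' @param path file path
#' @return tibble of stress samples
#' @export
read_stress_samples <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  st <- as_tibble(raw) |>
    mutate(timestamp = .as_instant(.data$timestamp),
           physician_id = as.character(.data$physician_id),
           score = suppressWarnings(as.integer(.data$score)),
           activity_flag = as.logical(.data$activity_flag))
  bad <- !is.na(st$score) & (st$score < 0 | st$score > 100)
  if (any(bad)) abort("stress scores must lie in [0, 100]")
  st |> arrange(.data$physician_id, .data$timestamp)
}

#' Write the hourly usage table as tidy CSV
#'
#' @param usage output of [hourly_usage()]
#' @param path destination path
#' @return `path`, invisibly
#' @export
write_hourly_usage <- function(usage, path) {
  out <- usage
  out$bin_start <- format(out$bin_start, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
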