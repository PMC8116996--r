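#' Hourly stress-duration summaries from 3-minute stress samples
#'
#' Each wearable sample is a 3-minute average stress score on a 0-100
#' scale. A sample contributes its minutes as *valid* when a score is
#' present and the device registered no physical activity (HRV is not a
#' reliable stress signal during movement); it contributes the same
#' minutes as *stress* when additionally the score exceeds
#' `stress_threshold` (medium/high stress, default >50). Scores in the low
#' band (25-50) and rest band (<25) are valid but not stress. Samples are
#' clipped to hour-bin boundaries, so partial-bin edge samples contribute
#' only their in-bin minutes.
#'
#' @param samples tibble with `physician_id`, `timestamp` (sample window
#'   start, POSIXct), `score` (0-100 or `NA`), `activity_flag` (logical)
#' @param stress_threshold score above which minutes count as stress
#'   (default 50)
#' @param sample_minutes duration of one sample window (default 3)
#' @param bin_anchor hour-bin anchor in minutes past the hour (default 30)
#' @return tibble per physician-hour: `physician_id`, `date`, `bin_start`,
#'   `valid_minutes`, `stress_minutes`, `stress_fraction` (`NA` when no
#'   valid minutes)
#' @export
hourly_stress <- function(samples, stress_threshold = 50, sample_minutes = 3,
                          bin_anchor = 30) {
  if (nrow(samples) == 0) {
    return(tibble(physician_id = character(), date = as.Date(character()),
                  bin_start = .as_instant(character()), valid_minutes = numeric(),
                  stress_minutes = numeric(), stress_fraction = numeric()))
  }
  stopifnot(all(samples$score >= 0 & samples$score <= 100, na.rm = TRUE))
  kept <- samples |>
    filter(!.data$activity_flag, !is.na(.data$score))
  if (nrow(kept) == 0) {
    return(hourly_stress(samples[0, ], stress_threshold, sample_minutes,
                         bin_anchor))
  }
  first_bin <- .bin_start(kept$timestamp, bin_anchor)
  ends <- kept$timestamp + sample_minutes * 60
  n_bins <- floor(as.numeric(difftime(ends, first_bin, units = "hours")) - 1e-12) + 1L
  idx <- rep(seq_len(nrow(kept)), n_bins)
  k <- sequence(n_bins) - 1L
  bin_start <- first_bin[idx] + k * 3600
  piece <- (pmin(as.numeric(ends)[idx], as.numeric(bin_start) + 3600) -
              pmax(as.numeric(kept$timestamp)[idx], as.numeric(bin_start))) / 60
  tibble(physician_id = kept$physician_id[idx],
         bin_start = bin_start,
         minutes = piece,
         stress = kept$score[idx] > stress_threshold) |>
    filter(.data$minutes > 0) |>
    group_by(.data$physician_id, .data$bin_start) |>
    summarise(valid_minutes = sum(.data$minutes),
              stress_minutes = sum(.data$minutes[.data$stress]),
              .groups = "drop") |>
    mutate(date = .date_of(.data$bin_start),
           stress_fraction = ifelse(.data$valid_minutes > 0,
                                    .data$stress_minutes / .data$valid_minutes,
                                    NA_real_)) |>
    select("physician_id", "date", "bin_start", "valid_minutes",
           "stress_minutes", "stress_fraction")
}

#' Stress duration as a percentage of valid measurement time
#'
#' @param stress_minutes minutes of medium/high stress
#' @param valid_minutes minutes of valid HRV measurement
#' @param digits rounding for presentation; `NULL` keeps full precision
#' @return percentage (0-100); `NA` when `valid_minutes` is 0
#' @examples
#' stress_fraction(80, 243)  # 33
#' stress_fraction(47, 265)  # 18
#' @export
stress_fraction <- function(stress_minutes, valid_minutes, digits = 0) {
  pct <- ifelse(valid_minutes > 0, 100 * stress_minutes / valid_minutes,
                NA_real_)
  if (is.null(digits)) pct else .round_half_up(pct, digits)
}

# round half away from zero, matching how percentages are presented
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Daily stress summaries
#'
#' Aggregates hourly summaries (already passed through the hourly validity
#' filter or not, as supplied) to one row per physician-day.
#'
#' @param hours output of [hourly_stress()]
#' @return tibble: `physician_id`, `date`, `valid_minutes`,
#'   `stress_minutes`, `stress_fraction`
#' @export
daily_stress <- function(hours) {
  hours |>
    group_by(.data$physician_id, .data$date) |>
    summarise(valid_minutes = sum(.data$valid_minutes),
              stress_minutes = sum(.data$stress_minutes), .groups = "drop") |>
    mutate(stress_fraction = ifelse(.data$valid_minutes > 0,
                                    .data$stress_minutes / .data$valid_minutes,
                                    NA_real_))
}

#' Apply measurement-validity filters with a removal report
#'
#' Hourly stress measures require at least `min_hour_valid` valid minutes
#' in the hour (guards against overestimating stress duration as a share
#' of a tiny measurement window). Daily measures require at least
#' `min_day_valid` valid minutes, a scheduled workday, and some inbox
#' activity. Each stage is reported as (input n, removed n, % removed).
#'
#' @param hours output of [hourly_stress()]
#' @param days tibble of day summaries carrying `physician_id`, `date`,
#'   `valid_minutes`, plus `workday` (logical) and `inbox_minutes` used by
#'   the day-level filters; pass `NULL` to filter hours only
#' @param min_hour_valid minimum valid minutes per hour (default 20)
#' @param min_day_valid minimum valid minutes per day (default 120)
#' @return list with `hours` (retained), `days` (retained, if supplied) and
#'   `report` (tibble: `stage`, `n_input`, `n_removed`, `pct_removed`)
#' @export
apply_validity_filters <- function(hours, days = NULL, min_hour_valid = 20,
                                   min_day_valid = 120) {
  keep_h <- hours$valid_minutes >= min_hour_valid
  report <- tibble(stage = "hours_min_valid",
                   n_input = nrow(hours),
                   n_removed = sum(!keep_h),
                   pct_removed = .round_half_up(100 * sum(!keep_h) /
                                                  max(1, nrow(hours)), 2))
  out <- list(hours = hours[keep_h, , drop = FALSE])
  if (!is.null(days)) {
    d <- days
    for (stage in c("days_min_valid", "days_workday", "days_inbox")) {
      keep <- switch(stage,
                     days_min_valid = d$valid_minutes >= min_day_valid,
                     days_workday = d$workday,
                     days_inbox = d$inbox_minutes > 0)
      report <- bind_rows(report, tibble(
        stage = stage, n_input = nrow(d), n_removed = sum(!keep),
        pct_removed = .round_half_up(100 * sum(!keep) / max(1, nrow(d)), 2)))
      d <- d[keep, , drop = FALSE]
    }
    out$days <- d
  }
  out$report <- report
  out
}

#' Cohort mean stress fraction by clock hour
#'
#' The hourly stress curve behind the daily "3-wave" stress pattern: for
#' each anchored clock hour, the mean stress fraction across all retained
#' physician-hours, with SD and SE. Feed hours that already passed the
#' 20-minute validity filter.
#'
#' @param hours filtered output of [hourly_stress()]
#' @return tibble per clock bin: `bin_label`, `bin_min` (minutes from
#'   midnight of bin start), `n`, `mean_fraction`, `sd_fraction`,
#'   `se_fraction`
#' @export
daily_stress_curve <- function(hours) {
  hours |>
    filter(!is.na(.data$stress_fraction)) |>
    mutate(bin_label = .bin_label(.data$bin_start),
           bin_min = .min_of_day(.data$bin_start)) |>
    group_by(.data$bin_label, .data$bin_min) |>
    summarise(n = dplyr::n(),
              mean_fraction = mean(.data$stress_fraction),
              sd_fraction = ifelse(dplyr::n() > 1, sd(.data$stress_fraction), 0),
              se_fraction = .data$sd_fraction / sqrt(dplyr::n()),
              .groups = "drop") |>
    arrange(.data$bin_min)
}

#' Work-hours stress duration per physician-day
#'
#' Sums stress and valid minutes over hour bins that intersect a scheduled
#' shift, using only hours that passed the hourly validity filter.
#'
#' @param hours filtered output of [hourly_stress()]
#' @param schedule a [work_schedule()]
#' @return tibble: `physician_id`, `date`, `work_valid_minutes`,
#'   `work_stress_minutes`, `work_stress_fraction`
#' @export
work_hours_stress <- function(hours, schedule = work_schedule()) {
  if (nrow(hours) == 0) {
    return(tibble(physician_id = character(), date = as.Date(character()),
                  work_valid_minutes = numeric(), work_stress_minutes = numeric(),
                  work_stress_fraction = numeric()))
  }
  sched <- as_tibble(schedule)
  hours |>
    mutate(wday = .wday_num(.data$date),
           bin_min = .min_of_day(.data$bin_start)) |>
    inner_join(sched, by = "wday", relationship = "many-to-many") |>
    filter(.data$bin_min < .data$shift_end,
           .data$bin_min + 60 > .data$shift_start) |>
    distinct(.data$physician_id, .data$bin_start, .keep_all = TRUE) |>
    group_by(.data$physician_id, .data$date) |>
    summarise(work_valid_minutes = sum(.data$valid_minutes),
              work_stress_minutes = sum(.data$stress_minutes),
              .groups = "drop") |>
    mutate(work_stress_fraction = ifelse(.data$work_valid_minutes > 0,
                                         .data$work_stress_minutes /
                                           .data$work_valid_minutes, NA_real_))
}
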