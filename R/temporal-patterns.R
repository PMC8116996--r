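#' Split daily inbox time by relation to scheduled work hours
#'
#' Every inbox minute of a physician-day is classified as (1) inside a
#' scheduled shift, (2) outside shifts but part of an activity run
#' adjoining a shift (within `contiguity_gap` minutes of a shift
#' boundary), or (3) outside shifts and detached from them (for example
#' late-evening work). The three components always sum to the day's total
#' inbox minutes. On days with no scheduled shifts all minutes fall
#' outside work hours.
#'
#' Out-of-hours activity runs are maximal chains of inbox intervals whose
#' gaps do not exceed `block_gap` minutes; a run is contiguous when the
#' gap between the run and the nearest shift is at most `contiguity_gap`.
#'
#' @param intervals inbox intervals (tibble with `physician_id`, `start`
#'   POSIXct, `minutes`), e.g. [sessionize()] output filtered to
#'   `category == "INBOX"`
#' @param schedule a [work_schedule()]
#' @param contiguity_gap minutes from a shift boundary within which an
#'   out-of-hours run still counts as contiguous (default 60)
#' @param block_gap maximum gap in minutes between intervals of one
#'   activity run (default 15)
#' @return tibble per physician-day: `physician_id`, `date`, `in_hours_min`,
#'   `contiguous_after_min`, `noncontiguous_after_min`, `total_inbox_min`,
#'   and proportions `p_in_hours`, `p_contiguous`, `p_noncontiguous`
#'   (`NA` when the day has no inbox time)
#' @export
split_by_work_hours <- function(intervals, schedule = work_schedule(),
                                contiguity_gap = 60, block_gap = 15) {
  empty <- tibble(physician_id = character(), date = as.Date(character()),
                  in_hours_min = numeric(), contiguous_after_min = numeric(),
                  noncontiguous_after_min = numeric(), total_inbox_min = numeric(),
                  p_in_hours = numeric(), p_contiguous = numeric(),
                  p_noncontiguous = numeric())
  if (nrow(intervals) == 0) return(empty)
  iv <- intervals |>
    mutate(date = .date_of(.data$start),
           s = .min_of_day(.data$start),
           e = .data$s + .data$minutes,
           wday = .wday_num(.data$date),
           .iv = dplyr::row_number())
  sched <- as_tibble(schedule)

  # minutes inside any shift
  in_tab <- iv |>
    inner_join(sched, by = "wday", relationship = "many-to-many") |>
    mutate(ov = .overlap_min(.data$s, .data$e, .data$shift_start, .data$shift_end)) |>
    group_by(.data$.iv) |>
    summarise(in_min = sum(.data$ov), .groups = "drop")
  iv <- iv |> left_join(in_tab, by = ".iv") |>
    mutate(in_min = coalesce(.data$in_min, 0))

  # out-of-hours segments: intersect intervals with the complement of the
  # shifts over the (extended) day
  out_regions <- purrr::map(1:7, function(w) {
    sh <- sched |> filter(.data$wday == w) |> arrange(.data$shift_start)
    bounds <- c(0, rbind(sh$shift_start, sh$shift_end), 2100)
    starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    tibble(wday = w, reg_start = starts, reg_end = ends) |>
      filter(.data$reg_end > .data$reg_start)
  }) |> list_rbind()
  segs <- iv |>
    inner_join(out_regions, by = "wday", relationship = "many-to-many") |>
    mutate(seg_s = pmax(.data$s, .data$reg_start),
           seg_e = pmin(.data$e, .data$reg_end)) |>
    filter(.data$seg_e > .data$seg_s)

  # chain out-of-hours segments into activity runs, classify runs by their
  # gap to the nearest shift
  out_tab <- if (nrow(segs) == 0) {
    tibble(physician_id = character(), date = as.Date(character()),
           contiguous_after_min = numeric(), noncontiguous_after_min = numeric())
  } else {
    runs <- segs |>
      arrange(.data$physician_id, .data$date, .data$seg_s) |>
      group_by(.data$physician_id, .data$date) |>
      mutate(run = cumsum(coalesce(.data$seg_s - dplyr::lag(cummax(.data$seg_e)),
                                   0) > block_gap)) |>
      group_by(.data$physician_id, .data$date, .data$wday, .data$run) |>
      summarise(run_s = min(.data$seg_s), run_e = max(.data$seg_e),
                minutes = sum(.data$seg_e - .data$seg_s), .groups = "drop")
    gaps <- runs |>
      left_join(sched, by = "wday", relationship = "many-to-many") |>
      mutate(gap = pmax(0, .data$shift_start - .data$run_e,
                        .data$run_s - .data$shift_end)) |>
      group_by(.data$physician_id, .data$date, .data$run) |>
      summarise(gap = ifelse(all(is.na(.data$gap)), Inf,
                             min(.data$gap, na.rm = TRUE)), .groups = "drop")
    runs |>
      left_join(gaps, by = c("physician_id", "date", "run")) |>
      mutate(contiguous = .data$gap <= contiguity_gap) |>
      group_by(.data$physician_id, .data$date) |>
      summarise(contiguous_after_min = sum(.data$minutes[.data$contiguous]),
                noncontiguous_after_min = sum(.data$minutes[!.data$contiguous]),
                .groups = "drop")
  }

  iv |>
    group_by(.data$physician_id, .data$date) |>
    summarise(in_hours_min = sum(.data$in_min),
              total_inbox_min = sum(.data$minutes), .groups = "drop") |>
    left_join(out_tab, by = c("physician_id", "date")) |>
    mutate(contiguous_after_min = coalesce(.data$contiguous_after_min, 0),
           noncontiguous_after_min = coalesce(.data$noncontiguous_after_min, 0),
           p_in_hours = ifelse(.data$total_inbox_min > 0,
                               .data$in_hours_min / .data$total_inbox_min, NA_real_),
           p_contiguous = ifelse(.data$total_inbox_min > 0,
                                 .data$contiguous_after_min / .data$total_inbox_min,
                                 NA_real_),
           p_noncontiguous = ifelse(.data$total_inbox_min > 0,
                                    .data$noncontiguous_after_min / .data$total_inbox_min,
                                    NA_real_)) |>
    select(dplyr::all_of(names(empty)))
}

#' Merge inbox intervals into work blocks
#'
#' Intervals separated by gaps of at most `block_gap` minutes are merged
#' into one block; a block's inbox minutes are the sum of its member
#' intervals (gaps inside a block are not counted as inbox time).
#'
#' @inheritParams split_by_work_hours
#' @param block_gap maximum within-block gap in minutes (default 15)
#' @return tibble per block: `physician_id`, `date`, `block`,
#'   `block_start`, `block_end` (minutes from midnight), `inbox_minutes`
#' @export
detect_blocks <- function(intervals, block_gap = 15) {
  if (nrow(intervals) == 0) {
    return(tibble(physician_id = character(), date = as.Date(character()),
                  block = integer(), block_start = numeric(),
                  block_end = numeric(), inbox_minutes = numeric()))
  }
  intervals |>
    mutate(date = .date_of(.data$start),
           s = .min_of_day(.data$start),
           e = .data$s + .data$minutes) |>
    arrange(.data$physician_id, .data$date, .data$s) |>
    group_by(.data$physician_id, .data$date) |>
    mutate(block = cumsum(coalesce(.data$s - dplyr::lag(cummax(.data$e)), 0) >
                            block_gap) + 1L) |>
    group_by(.data$physician_id, .data$date, .data$block) |>
    summarise(block_start = min(.data$s), block_end = max(.data$e),
              inbox_minutes = sum(.data$minutes), .groups = "drop")
}

#' Daily inbox batching indicator
#'
#' A day is batched when the largest `max_blocks` blocks cover at least
#' `coverage_threshold` of the day's total inbox minutes -- i.e. inbox
#' work was concentrated in a few dedicated chunks rather than spread in
#' continual checks. Days with no inbox time are not batched.
#'
#' @param blocks output of [detect_blocks()]
#' @param coverage_threshold fraction of daily inbox time the top blocks
#'   must cover (default 0.70)
#' @param max_blocks number of blocks allowed to carry that coverage
#'   (default 3)
#' @return tibble per physician-day: `physician_id`, `date`, `n_blocks`,
#'   `coverage` (fraction in top blocks), `batched` (logical)
#' @export
is_batched_day <- function(blocks, coverage_threshold = 0.70, max_blocks = 3) {
  stopifnot(coverage_threshold > 0, coverage_threshold <= 1, max_blocks >= 1)
  blocks |>
    group_by(.data$physician_id, .data$date) |>
    summarise(n_blocks = dplyr::n(),
              total = sum(.data$inbox_minutes),
              top = sum(sort(.data$inbox_minutes, decreasing = TRUE)[
                seq_len(min(max_blocks, dplyr::n()))]),
              .groups = "drop") |>
    mutate(coverage = ifelse(.data$total > 0, .data$top / .data$total, 0),
           batched = .data$total > 0 & .data$coverage >= coverage_threshold) |>
    select("physician_id", "date", "n_blocks", "coverage", "batched")
}
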