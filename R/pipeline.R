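#' Run the full inbox-stress analysis pipeline
#'
#' Orchestrates every stage on raw data streams: sessionization and hourly
#' feature extraction from log events, temporal splitting and batching of
#' inbox work against the clinic schedule, validity-filtered stress
#' summaries, physician profiles and Gaussian-mixture work-pattern groups,
#' group comparisons, and the Poisson mixed-effects stress association
#' model on retained physician-days. Every filter stage is accounted for
#' in the removal report.
#'
#' @param x an `inbox_cohort` from [generate_cohort()], or a list with
#'   `events`, `stress`, `roster`, `schedule` components (e.g. read via
#'   [read_log_events()] and friends)
#' @param idle_cutoff,bin_anchor sessionization and binning settings
#' @param block_gap,contiguity_gap temporal-pattern settings (minutes)
#' @param coverage_threshold,max_blocks batching rule
#' @param stress_threshold score above which minutes count as stress
#' @param min_hour_valid,min_day_valid validity filters (minutes)
#' @param K mixture components for clustering
#' @param seed seed for the clustering fit
#' @param fit_model fit the association model (set `FALSE` to skip)
#' @return list of class `inbox_pipeline` with components `usage`,
#'   `splits`, `blocks`, `batched`, `stress_hours`, `stress_days`,
#'   `filter_report`, `stress_curve`, `work_stress`, `profiles`,
#'   `clusters`, `comparison`, `model_frame`, `model`, `descriptives`
#' @export
run_pipeline <- function(x, idle_cutoff = 5, bin_anchor = 30,
                         block_gap = 15, contiguity_gap = 60,
                         coverage_threshold = 0.70, max_blocks = 3,
                         stress_threshold = 50, min_hour_valid = 20,
                         min_day_valid = 120, K = 3, seed = 1,
                         fit_model = TRUE) {
  events <- x$events; stress <- x$stress; roster <- x$roster
  schedule <- x$schedule %||% work_schedule()
  if (is.null(events) || is.null(stress)) {
    abort("x must carry `events` and `stress` components")
  }

  usage <- hourly_usage(events, idle_cutoff, bin_anchor)
  intervals <- sessionize(events, idle_cutoff)
  inbox_iv <- intervals |> filter(.data$category == "INBOX")

  workday <- is_workday(unique(intervals$date), schedule)
  workdays <- unique(intervals$date)[workday]

  splits <- split_by_work_hours(inbox_iv |>
                                  filter(.date_of(.data$start) %in% workdays),
                                schedule, contiguity_gap, block_gap)
  blocks <- detect_blocks(inbox_iv, block_gap)
  batched <- is_batched_day(blocks, coverage_threshold, max_blocks)

  nonworkday_inbox <- inbox_iv |>
    filter(!(.date_of(.data$start) %in% workdays)) |>
    group_by(.data$physician_id, date = .date_of(.data$start)) |>
    summarise(m = sum(.data$minutes), .groups = "drop") |>
    group_by(.data$physician_id) |>
    summarise(nonworkday_inbox_min = mean(.data$m), .groups = "drop")

  stress_hours <- hourly_stress(stress, stress_threshold,
                                bin_anchor = bin_anchor)
  usage_daily <- usage |>
    group_by(.data$physician_id, .data$date) |>
    summarise(across(c("minutes_ehr", "minutes_inbox", "minutes_patient",
                       "minutes_result", "minutes_request", "minutes_admin"),
                     sum),
              n_window_switches = sum(.data$n_window_switches),
              n_tasks = sum(.data$n_tasks), .groups = "drop")
  stress_days <- daily_stress(stress_hours) |>
    left_join(usage_daily |> select("physician_id", "date", "minutes_inbox"),
              by = c("physician_id", "date")) |>
    mutate(inbox_minutes = coalesce(.data$minutes_inbox, 0),
           workday = is_workday(.data$date, schedule)) |>
    select(-"minutes_inbox")
  filtered <- apply_validity_filters(stress_hours, stress_days,
                                     min_hour_valid, min_day_valid)
  stress_curve <- daily_stress_curve(
    filtered$hours |> filter(is_workday(.data$date, schedule)))
  work_stress <- work_hours_stress(filtered$hours, schedule)

  profiles <- physician_profiles(splits, batched |>
                                   filter(.data$date %in% workdays),
                                 usage |> filter(.data$date %in% workdays),
                                 roster, nonworkday_inbox)
  clusters <- fit_mixture(profiles, K = K, seed = seed)
  comparison <- compare_groups(
    profiles, tidy(clusters),
    vars = intersect(c("p_in_hours", "p_contiguous", "p_noncontiguous",
                       "work_inbox_min", "after_inbox_min",
                       "nonworkday_inbox_min", "share_patient",
                       "share_result", "share_request", "share_admin",
                       "time_per_message", "batch_frac", "age", "sex",
                       "years_experience", "fte"),
                     names(profiles)))

  model_frame <- NULL; model <- NULL
  if (fit_model) {
    days <- .assemble_model_days(filtered$days, work_stress, usage, splits,
                                 usage_daily, batched, roster, schedule)
    if (nrow(days) >= 10 && dplyr::n_distinct(days$physician_id) >= 2) {
      model_frame <- build_model_frame(days)
      model <- tryCatch(fit_poisson_mixed(model_frame),
                        error = function(e) {
                          warn(paste("association model failed:",
                                     conditionMessage(e)))
                          NULL
                        })
    }
  }

  out <- list(usage = usage, splits = splits, blocks = blocks,
              batched = batched, stress_hours = stress_hours,
              stress_days = filtered$days, filter_report = filtered$report,
              stress_curve = stress_curve, work_stress = work_stress,
              profiles = profiles, clusters = clusters,
              comparison = comparison, model_frame = model_frame,
              model = model, schedule = schedule)
  out$descriptives <- summarize_descriptives(out)
  class(out) <- "inbox_pipeline"
  out
}

# covariates for the physician-day association model, restricted to days
# retained by all validity filters
.assemble_model_days <- function(retained_days, work_stress, usage, splits,
                                 usage_daily, batched, roster, schedule) {
  work_usage <- .work_hours_usage(usage, schedule)
  retained_days |>
    select("physician_id", "date") |>
    inner_join(work_stress, by = c("physician_id", "date")) |>
    filter(.data$work_valid_minutes > 0) |>
    left_join(work_usage, by = c("physician_id", "date")) |>
    left_join(splits |> select("physician_id", "date", "p_in_hours"),
              by = c("physician_id", "date")) |>
    left_join(usage_daily, by = c("physician_id", "date")) |>
    left_join(batched |> select("physician_id", "date", "batched"),
              by = c("physician_id", "date")) |>
    left_join(roster, by = "physician_id") |>
    mutate(switch_rate = ifelse(.data$minutes_ehr > 0,
                                .data$n_window_switches / .data$minutes_ehr,
                                NA_real_),
           inbox_work_min = coalesce(.data$work_inbox_min, 0),
           noninbox_work_min = coalesce(.data$work_ehr_min, 0) -
             coalesce(.data$work_inbox_min, 0),
           after_prop = 1 - coalesce(.data$p_in_hours, 1),
           patient_prop = ifelse(.data$minutes_inbox > 0,
                                 .data$minutes_patient / .data$minutes_inbox,
                                 0),
           batched = as.integer(coalesce(.data$batched, FALSE))) |>
    filter(!is.na(.data$switch_rate)) |>
    select("physician_id", "date", "work_stress_minutes",
           "work_valid_minutes", "switch_rate", "inbox_work_min",
           "noninbox_work_min", "after_prop", "patient_prop", "batched",
           dplyr::any_of(c("fte", "age", "sex")))
}

# EHR/inbox minutes falling in shift-intersecting hour bins
.work_hours_usage <- function(usage, schedule) {
  sched <- as_tibble(schedule)
  usage |>
    mutate(wday = .wday_num(.data$date),
           bin_min = .min_of_day(.data$bin_start)) |>
    inner_join(sched, by = "wday", relationship = "many-to-many") |>
    filter(.data$bin_min < .data$shift_end,
           .data$bin_min + 60 > .data$shift_start) |>
    distinct(.data$physician_id, .data$bin_start, .keep_all = TRUE) |>
    group_by(.data$physician_id, .data$date) |>
    summarise(work_ehr_min = sum(.data$minutes_ehr),
              work_inbox_min = sum(.data$minutes_inbox), .groups = "drop")
}

#' Headline cohort descriptives
#'
#' Cohort means and SDs (across physicians) of daily EHR and inbox hours
#' on workdays, nonworkday EHR/inbox minutes, and message-type shares of
#' inbox time.
#'
#' @param pipeline an `inbox_pipeline` (or a list with `usage` and
#'   `schedule`)
#' @return tidy tibble: `statistic`, `unit`, `mean`, `sd`
#' @export
summarize_descriptives <- function(pipeline) {
  usage <- pipeline$usage
  schedule <- pipeline$schedule %||% work_schedule()
  daily <- usage |>
    group_by(.data$physician_id, .data$date) |>
    summarise(across(c("minutes_ehr", "minutes_inbox", "minutes_patient",
                       "minutes_result", "minutes_request", "minutes_admin"),
                     sum), .groups = "drop") |>
    mutate(workday = is_workday(.data$date, schedule))
  per_phys <- daily |>
    group_by(.data$physician_id) |>
    summarise(
      ehr_h_workday = mean(.data$minutes_ehr[.data$workday]) / 60,
      inbox_h_workday = mean(.data$minutes_inbox[.data$workday]) / 60,
      ehr_min_nonworkday = ifelse(any(!.data$workday),
                                  mean(.data$minutes_ehr[!.data$workday]), NA),
      inbox_min_nonworkday = ifelse(any(!.data$workday),
                                    mean(.data$minutes_inbox[!.data$workday]),
                                    NA),
      share_patient = sum(.data$minutes_patient) / sum(.data$minutes_inbox),
      share_result = sum(.data$minutes_result) / sum(.data$minutes_inbox),
      share_request = sum(.data$minutes_request) / sum(.data$minutes_inbox),
      share_admin = sum(.data$minutes_admin) / sum(.data$minutes_inbox),
      .groups = "drop")
  stats_of <- function(x, nm, unit) {
    tibble(statistic = nm, unit = unit, mean = mean(x, na.rm = TRUE),
           sd = sd(x, na.rm = TRUE))
  }
  bind_rows(
    stats_of(per_phys$ehr_h_workday, "workday EHR time", "hours/day"),
    stats_of(per_phys$inbox_h_workday, "workday inbox time", "hours/day"),
    stats_of(per_phys$ehr_min_nonworkday, "nonworkday EHR time", "min/day"),
    stats_of(per_phys$inbox_min_nonworkday, "nonworkday inbox time",
             "min/day"),
    stats_of(100 * per_phys$share_patient, "patient-message share of inbox time", "%"),
    stats_of(100 * per_phys$share_result, "result share of inbox time", "%"),
    stats_of(100 * per_phys$share_request, "request share of inbox time", "%"),
    stats_of(100 * per_phys$share_admin, "admin share of inbox time", "%"))
}

#' @export
print.inbox_pipeline <- function(x, ...) {
  cat("<inbox_pipeline>\n")
  cat(sprintf("  %d physicians, %d hourly usage rows\n",
              dplyr::n_distinct(x$usage$physician_id), nrow(x$usage)))
  cat(sprintf("  clustering: K = %d, silhouette = %.2f\n", x$clusters$K,
              x$clusters$silhouette))
  if (!is.null(x$model)) {
    cat(sprintf("  model: %d physician-days, marginal R2 = %.2f, conditional R2 = %.2f\n",
                x$model$n, x$model$marginal_r2, x$model$conditional_r2))
  }
  invisible(x)
}

#' Experience-sampling compliance summary
#'
#' Momentary self-report prompts are modelled only through their summary
#' outputs: how many of the scheduled prompts went unanswered, as a
#' percentage (whole-percent, half-up).
#'
#' @param n_missed mean number of missed prompts per physician
#' @param n_prompts prompts scheduled over the study period
#' @return tibble with `n_missed`, `n_prompts`, `missed_pct`
#' @export
experience_sampling_summary <- function(n_missed, n_prompts) {
  stopifnot(n_prompts > 0, n_missed >= 0, n_missed <= n_prompts)
  tibble(n_missed = n_missed, n_prompts = n_prompts,
         missed_pct = .round_half_up(100 * n_missed / n_prompts))
}
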