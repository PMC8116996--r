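# shared builders for tiny in-code fixtures

ts_at <- function(hhmm, date = "2023-03-06") {
  if (length(hhmm) == 0) return(as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"))
  as.POSIXct(paste(date, hhmm), tz = "UTC")
}

# event stream with sensible defaults; `times` are POSIXct or "HH:MM"
make_events <- function(times, physician_id = "p1", category = "INBOX",
                        message_type = NULL, window_id = "w1",
                        is_task_completion = FALSE, date = "2023-03-06") {
  if (is.character(times)) times <- ts_at(times, date)
  n <- length(times)
  if (is.null(message_type)) {
    message_type <- ifelse(category == "OTHER_EHR", "NONE", "RESULT")
  }
  tibble::tibble(
    timestamp = times,
    physician_id = rep_len(physician_id, n),
    category = rep_len(category, n),
    message_type = rep_len(message_type, n),
    window_id = rep_len(window_id, n),
    is_task_completion = rep_len(is_task_completion, n))
}

# inbox interval tibble from (start "HH:MM", minutes) pairs
make_intervals <- function(starts, minutes, physician_id = "p1",
                           date = "2023-03-06", category = "INBOX") {
  start <- ts_at(starts, date)
  tibble::tibble(
    physician_id = rep_len(physician_id, length(start)),
    date = as.Date(date),
    start = start,
    end = start + minutes * 60,
    minutes = minutes,
    category = rep_len(category, length(start)),
    message_type = "RESULT")
}

# stress samples every 3 minutes from `from`, one physician
make_samples <- function(scores, from = "09:30", physician_id = "p1",
                         date = "2023-03-06", activity_flag = FALSE) {
  n <- length(scores)
  tibble::tibble(
    physician_id = physician_id,
    timestamp = ts_at(from, date) + (seq_len(n) - 1) * 180,
    score = scores,
    activity_flag = rep_len(activity_flag, n))
}

# a small, fast cohort for pipeline-level tests
small_cohort_config <- function(seed = 7) {
  cohort_config(seed = seed, group_sizes = c(3, 4, 5))
}

# brute-force second-by-second attribution oracle for sessionization:
# each second belongs to the most recent event if it occurred within
# `cutoff` minutes before it
brute_force_attributed <- function(times, cutoff = 5) {
  secs <- as.numeric(times)
  total <- 0
  for (i in seq_along(secs)) {
    horizon <- secs[i] + cutoff * 60
    nxt <- if (i < length(secs)) secs[i + 1] else Inf
    total <- total + (min(horizon, nxt) - secs[i])
  }
  total / 60
}

# union-find oracle for block merging: intervals are nodes, edges connect
# intervals whose gap is <= block_gap; blocks = connected components
union_find_blocks <- function(start_min, end_min, block_gap = 15) {
  n <- length(start_min)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      gap <- max(start_min[i], start_min[j]) - min(end_min[i], end_min[j])
      if (gap <= block_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# profiles drawn straight from the group prototypes (no pipeline noise)
draw_prototype_profiles <- function(seed, sizes = c(10, 17, 20)) {
  proto <- group_prototypes()
  withr::with_seed(seed, {
    P <- do.call(rbind, lapply(seq_len(nrow(proto)), function(g) {
      inboxstress:::.draw_simplex(sizes[g], proto[g, ])
    }))
    tibble::tibble(
      physician_id = sprintf("p%02d", seq_len(sum(sizes))),
      group_true = rep(proto$group, sizes),
      p_in_hours = P[, "p_in"],
      p_noncontiguous = P[, "p_noncontig"],
      p_contiguous = P[, "p_contig"])
  })
}

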