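#' Work-pattern group prototypes
#'
#' The three behavioural prototypes the cohort generator draws physicians
#' from, one per temporal work-pattern group: group 1 does much of its
#' inbox work detached from clinic hours (late evenings / early
#' mornings), group 2 works almost entirely inside scheduled hours, group
#' 3 extends work contiguously past the shift edges. Each prototype
#' carries the mean and SD of the daily temporal split of inbox time, the
#' work-hours and after-hours inbox durations (minutes), nonworkday inbox
#' minutes, the message-type time mix, per-message handling time,
#' batching propensity, and the target work-hours stress fraction.
#'
#' @return tibble, one row per group
#' @export
group_prototypes <- function() {
  tibble(
    group = 1:3,
    p_in_mean = c(0.37, 0.82, 0.62),
    p_in_sd = c(0.12, 0.08, 0.09),
    p_noncontig_mean = c(0.42, 0.01, 0.12),
    p_noncontig_sd = c(0.11, 0.02, 0.05),
    p_contig_mean = c(0.21, 0.17, 0.26),
    p_contig_sd = c(0.11, 0.07, 0.13),
    work_inbox_mean = c(25.36, 47.97, 42.13),
    work_inbox_sd = c(13.03, 13.35, 16.56),
    after_inbox_mean = c(41.37, 10.91, 26.97),
    after_inbox_sd = c(13.81, 5.63, 13.26),
    nonworkday_inbox_mean = c(32.74, 11.13, 6.54),
    nonworkday_inbox_sd = c(37.46, 19.69, 11.3),
    mix_patient = c(0.32, 0.35, 0.42),
    mix_result = c(0.30, 0.32, 0.26),
    mix_request = c(0.24, 0.20, 0.21),
    mix_admin = c(0.14, 0.13, 0.11),
    tpm_mean = c(0.46, 0.35, 0.38),
    tpm_sd = c(0.11, 0.06, 0.07),
    batch_prob = c(0.50, 0.06, 0.30),
    stress_frac_mean = c(0.33, 0.18, 0.22),
    stress_frac_sd = c(0.27, 0.18, 0.24)
  )
}

#' Cohort generator configuration
#'
#' Bundles every knob of the synthetic cohort: group sizes, study window,
#' schedule, the event-emission mechanics that realize attributed minutes
#' exactly under the sessionization rule, sensor-dropout structure, and
#' the 3-wave stress model. Defaults reproduce the study conditions
#' (47 physicians in groups of 10/17/20, 5 workdays + 2 nonworkdays,
#' 08:30-17:30 split shifts).
#'
#' @param seed integer seed for the whole cohort
#' @param group_sizes physicians per prototype group
#' @param n_workdays,n_nonworkdays days per physician
#' @param start_date first study day (a Monday by default)
#' @param schedule a [work_schedule()]
#' @param prototypes a [group_prototypes()]-shaped tibble
#' @param idle_cutoff sessionization idle cutoff the generator assumes
#'   when realizing run lengths (minutes)
#' @param events_per_min log-event density inside a non-inbox activity run
#' @param inbox_events_per_min log-event density inside an inbox run;
#'   higher than non-inbox work because every handled message is an event
#'   and inbox interaction is click-dense
#' @param switch_rate target window switches per minute of EHR use
#' @param ehr_noninbox_mean,ehr_noninbox_sd daily non-inbox EHR minutes on
#'   workdays (between-physician distribution)
#' @param day_alr_sd day-to-day noise SD of the temporal split in alr
#'   space
#' @param day_total_cv day-to-day coefficient of variation of daily totals
#' @param stress_sigma_e,stress_sigma_u score-scale SDs of sample noise
#'   and of the physician intercept
#' @param first_hour_target cohort mean stress fraction in the first
#'   scheduled work hour the wave amplitude is calibrated to
#' @param dropout list of sensor-dropout settings (see source); set
#'   `dropout = NULL` for a gap-free device
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(seed = 1, group_sizes = c(10, 17, 20),
                          n_workdays = 5, n_nonworkdays = 2,
                          start_date = as.Date("2023-03-06"),
                          schedule = work_schedule(),
                          prototypes = group_prototypes(),
                          idle_cutoff = 5, events_per_min = 8,
                          inbox_events_per_min = 14, switch_rate = 4.25,
                          ehr_noninbox_mean = 145, ehr_noninbox_sd = 34,
                          day_alr_sd = 0.25, day_total_cv = 0.15,
                          stress_sigma_e = 12, stress_sigma_u = 10,
                          first_hour_target = 0.35,
                          dropout = list(short_rate = 30, short_mean = 14,
                                         long_rate = 1.5, long_mean = 60,
                                         activity_rate = 2,
                                         activity_mean = 35,
                                         night_off = TRUE)) {
  stopifnot(all(group_sizes >= 1), n_workdays >= 1, idle_cutoff > 0)
  if (.wday_num(start_date) != 1L) abort("start_date must be a Monday")
  structure(list(seed = seed, group_sizes = group_sizes,
                 n_workdays = n_workdays, n_nonworkdays = n_nonworkdays,
                 start_date = start_date, schedule = schedule,
                 prototypes = prototypes, idle_cutoff = idle_cutoff,
                 events_per_min = events_per_min,
                 inbox_events_per_min = inbox_events_per_min,
                 switch_rate = switch_rate,
                 ehr_noninbox_mean = ehr_noninbox_mean,
                 ehr_noninbox_sd = ehr_noninbox_sd,
                 day_alr_sd = day_alr_sd, day_total_cv = day_total_cv,
                 stress_sigma_e = stress_sigma_e,
                 stress_sigma_u = stress_sigma_u,
                 first_hour_target = first_hour_target,
                 dropout = dropout),
            class = "cohort_config")
}

# ---- simplex calibration -------------------------------------------------

# Gauss-Hermite nodes for 2-d logistic-normal moments
.gh_nodes <- function(k = 21) {
  h <- .gh_raw(k)
  list(x = h$x * sqrt(2), w = h$w / sqrt(pi))
}

# Hermite nodes/weights via the Golub-Welsch eigen decomposition
.gh_raw <- function(k) {
  i <- seq_len(k - 1)
  J <- diag(0, k)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

.ln_moments <- function(par, q) {
  a <- par[1:2]; s <- exp(par[3:4])
  y1 <- outer(a[1] + s[1] * q$x, rep(1, length(q$x)))
  y2 <- outer(rep(1, length(q$x)), a[2] + s[2] * q$x)
  den <- 1 + exp(y1) + exp(y2)
  w <- outer(q$w, q$w)
  p1 <- exp(y1) / den; p2 <- exp(y2) / den
  m1 <- sum(w * p1); m2 <- sum(w * p2)
  c(m1, m2, sqrt(sum(w * p1^2) - m1^2), sqrt(sum(w * p2^2) - m2^2))
}

.calib_cache <- new.env(parent = emptyenv())

# match a logistic-normal on the 3-simplex to target means/SDs of the
# first two parts; coordinates are alr(p1/p3), alr(p2/p3), independent
.alr_match <- function(mean3, sd2) {
  key <- paste(signif(c(mean3, sd2), 8), collapse = ",")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  q <- .gh_nodes(21)
  tgt <- c(mean3[1], mean3[2], sd2[1], sd2[2])
  obj <- function(par) sum((.ln_moments(par, q) / tgt - 1)^2)
  p0 <- c(log(mean3[1] / mean3[3]), log(mean3[2] / mean3[3]), log(0.3), log(0.3))
  o <- stats::optim(p0, obj, method = "Nelder-Mead",
                    control = list(maxit = 3000, reltol = 1e-12))
  out <- c(a1 = o$par[1], a2 = o$par[2], s1 = exp(o$par[3]),
           s2 = exp(o$par[4]))
  .calib_cache[[key]] <- out
  out
}

# draw n simplex points (in-hours, noncontig, contig) for one group
.draw_simplex <- function(n, proto_row, jitter_sd = 0) {
  par <- .alr_match(c(proto_row$p_in_mean, proto_row$p_noncontig_mean,
                      proto_row$p_contig_mean),
                    c(proto_row$p_in_sd, proto_row$p_noncontig_sd))
  y1 <- stats::rnorm(n, par["a1"], sqrt(par["s1"]^2 + jitter_sd^2))
  y2 <- stats::rnorm(n, par["a2"], sqrt(par["s2"]^2 + jitter_sd^2))
  e1 <- exp(y1); e2 <- exp(y2)
  den <- 1 + e1 + e2
  cbind(p_in = e1 / den, p_noncontig = e2 / den, p_contig = 1 / den)
}

# ---- stress-wave calibration --------------------------------------------

# three daily stress waves: first work hour, early afternoon, evening
.stress_wave <- function(t_hours, centers = c(9, 13.75, 20),
                         widths = c(0.8, 1.0, 1.5), rel = c(1, 0.65, 0.85)) {
  out <- 0
  for (k in seq_along(centers)) {
    out <- out + rel[k] * exp(-(t_hours - centers[k])^2 / (2 * widths[k]^2))
  }
  out
}

# solve per-group baselines and a common wave amplitude so that the
# expected work-hours stress fraction hits each group target and the
# cohort first-work-hour mean hits its target; probit inversion with the
# total score SD, thresholded at 50.5 to respect integer rounding
.calibrate_stress <- function(prototypes, group_sizes, schedule,
                              sigma_tot, first_hour_target) {
  sh <- .shifts_on(as.Date("2023-03-06"), schedule)
  tgrid <- unlist(purrr::map2(sh$shift_start, sh$shift_end,
                              function(s, e) seq(s + 1.5, e - 1.5, by = 3))) / 60
  first_hour <- seq(sh$shift_start[1] + 1.5, sh$shift_start[1] + 58.5,
                    by = 3) / 60
  thr <- 50.5
  frac <- function(base, A, tt) mean(stats::pnorm(
    (base + A * .stress_wave(tt) - thr) / sigma_tot))
  A <- 10
  base <- rep(40, nrow(prototypes))
  wts <- group_sizes / sum(group_sizes)
  for (iter in 1:8) {
    for (g in seq_len(nrow(prototypes))) {
      tg <- prototypes$stress_frac_mean[g]
      base[g] <- stats::uniroot(function(b) frac(b, A, tgrid) - tg,
                                c(-200, 200))$root
    }
    fh <- function(a) {
      cohort <- sum(wts * vapply(base, function(b) frac(b, a, first_hour),
                                 numeric(1)))
      cohort - first_hour_target
    }
    A_new <- tryCatch(stats::uniroot(fh, c(0, 80))$root, error = function(e) A)
    if (abs(A_new - A) < 1e-6) { A <- A_new; break }
    A <- A_new
  }
  list(base = base, amplitude = A)
}

# ---- run partition and placement ----------------------------------------

# split a minute amount into run lengths, each at least `quantum` minutes
# (the idle cutoff: shorter isolated runs cannot be realized exactly under
# last-event-carried-forward). Amounts below the quantum are realized as a
# single quantum-length run with probability T/quantum, keeping the
# expectation calibrated.
.split_runs <- function(total, quantum, mean_len, min_runs = 1) {
  if (total < quantum) {
    if (stats::runif(1) < total / quantum) return(quantum) else return(numeric(0))
  }
  k <- max(1, min(floor(total / quantum),
                  max(min_runs, round(total / mean_len))))
  extra <- total - quantum * k
  w <- stats::rgamma(k, 2); w <- w / sum(w)
  quantum + extra * w
}

# place runs inside windows with minimum gaps; windows is a tibble with
# w0/w1; returns tibble(start, len) or fewer runs if capacity forces merges
.place_runs <- function(lengths, windows, min_gap) {
  if (length(lengths) == 0) {
    return(tibble(start = numeric(0), len = numeric(0)))
  }
  caps <- windows$w1 - windows$w0
  # assign runs to windows greedily by remaining capacity
  assign <- integer(length(lengths))
  rem <- caps
  for (i in order(lengths, decreasing = TRUE)) {
    j <- which.max(rem)
    assign[i] <- j
    rem[j] <- rem[j] - lengths[i] - min_gap
  }
  out <- purrr::map(seq_len(nrow(windows)), function(j) {
    ls <- lengths[assign == j]
    if (length(ls) == 0) return(tibble(start = numeric(0), len = numeric(0)))
    ls <- ls[sample.int(length(ls))]
    k <- length(ls)
    cap <- caps[j]
    gap <- min_gap
    # shrink gaps (never below 2) and merge runs if the window is tight
    while (sum(ls) + gap * (k - 1) > cap && k > 1) {
      if (gap > 2) gap <- max(2, gap - 2)
      else { ls <- c(sum(ls[1:2]), ls[-(1:2)]); k <- length(ls) }
    }
    if (sum(ls) + gap * (k - 1) > cap) ls <- min(sum(ls), cap)
    k <- length(ls)
    free <- cap - sum(ls) - gap * (k - 1)
    cuts <- if (k > 0) {
      u <- stats::rgamma(k + 1, 1); u / sum(u) * free
    } else numeric(0)
    starts <- windows$w0[j] + cumsum(c(0, ls[-k] + gap)) + cumsum(cuts[seq_len(k)])
    tibble(start = starts, len = ls)
  }) |> list_rbind()
  out[order(out$start), ]
}

# ---- the generator -------------------------------------------------------

#' Generate a synthetic physician cohort
#'
#' Draws a roster, per-physician behavioural parameters from the group
#' prototypes, and emits the three raw data streams the pipeline ingests:
#' timestamped EHR log events, 3-minute wearable stress samples, and the
#' roster, plus a ground-truth record for recovery tests. The emission
#' mechanics are built around the sessionization rule so that the minutes
#' the pipeline attributes from the events equal the generated run lengths
#' exactly; every stochastic choice flows from the config seed, so a fixed
#' config reproduces the cohort bit for bit.
#'
#' @param config a [cohort_config()]
#' @return list of class `inbox_cohort`: `roster`, `events`, `stress`,
#'   `schedule`, `truth`, `config`
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  proto <- cfg$prototypes
  n_g <- cfg$group_sizes
  n_phys <- sum(n_g)
  ids <- sprintf("p%02d", seq_len(n_phys))
  groups <- rep(proto$group, n_g)

  sigma_tot <- sqrt(cfg$stress_sigma_e^2 + cfg$stress_sigma_u^2)
  stress_cal <- .calibrate_stress(proto, n_g, cfg$schedule, sigma_tot,
                                  cfg$first_hour_target)

  age <- pmin(pmax(stats::rnorm(n_phys, 43.83, 9.51), 31), 68)
  roster <- tibble(
    physician_id = ids,
    age = round(age, 1),
    sex = ifelse(stats::rbinom(n_phys, 1, 32 / 47) == 1, "F", "M"),
    years_experience = round(pmin(pmax(age - stats::rnorm(n_phys, 28, 4), 4),
                                  42), 1),
    fte = round(pmin(pmax(stats::rnorm(n_phys, 0.81, 0.14), 0.4), 1), 2))

  # physician-level behavioural parameters
  phys <- purrr::map(seq_len(nrow(proto)), function(g) {
    n <- n_g[g]; pr <- proto[g, ]
    P <- .draw_simplex(n, pr)
    total_mean <- pr$work_inbox_mean + pr$after_inbox_mean
    total_sd <- sqrt(pr$work_inbox_sd^2 + pr$after_inbox_sd^2)
    mix <- cbind(pr$mix_patient, pr$mix_result, pr$mix_request, pr$mix_admin)
    conc <- 60
    dir <- matrix(stats::rgamma(n * 4, rep(as.numeric(mix) * conc, each = n)),
                  nrow = n)
    dir <- dir / rowSums(dir)
    tibble(group = pr$group,
           p_in = P[, "p_in"], p_noncontig = P[, "p_noncontig"],
           p_contig = P[, "p_contig"],
           inbox_total = pmax(stats::rnorm(n, total_mean, total_sd), 0),
           tpm = pmax(stats::rnorm(n, pr$tpm_mean, pr$tpm_sd), 0.15),
           batcher = stats::rbinom(n, 1, pr$batch_prob) == 1,
           mix_patient = dir[, 1], mix_result = dir[, 2],
           mix_request = dir[, 3], mix_admin = dir[, 4],
           nonworkday_inbox = stats::rgamma(
             n,
             shape = (pr$nonworkday_inbox_mean / pr$nonworkday_inbox_sd)^2,
             scale = pr$nonworkday_inbox_sd^2 / pr$nonworkday_inbox_mean),
           stress_base = stress_cal$base[g],
           stress_u = stats::rnorm(n, 0, cfg$stress_sigma_u))
  }) |> list_rbind() |>
    mutate(physician_id = ids, .before = 1) |>
    mutate(noninbox_ehr = pmax(stats::rnorm(n_phys, cfg$ehr_noninbox_mean,
                                            cfg$ehr_noninbox_sd), 30))

  dates_work <- cfg$start_date + seq_len(cfg$n_workdays) - 1
  dates_off <- cfg$start_date + 5 + seq_len(cfg$n_nonworkdays) - 1
  all_dates <- c(dates_work, dates_off)

  day_tables <- purrr::map(seq_len(n_phys), function(i) {
    .physician_days(phys[i, ], dates_work, dates_off, cfg)
  })
  runs <- purrr::map(day_tables, "runs") |> list_rbind()
  truth_days <- purrr::map(day_tables, "truth") |> list_rbind()

  events <- .emit_events(runs, phys, cfg)
  stress <- .emit_stress(phys, all_dates, cfg, stress_cal)

  truth <- list(
    roster = roster |> mutate(group = groups),
    physicians = phys,
    days = truth_days,
    stress_calibration = c(as.list(stress_cal),
                           list(sigma_e = cfg$stress_sigma_e,
                                sigma_u = cfg$stress_sigma_u,
                                first_hour_target = cfg$first_hour_target,
                                group_targets = proto$stress_frac_mean)))

  structure(list(roster = roster, events = events, stress = stress,
                 schedule = cfg$schedule, truth = truth, config = cfg),
            class = "inbox_cohort")
}

# build the run table (start/len/category per activity run) and per-day
# truth for one physician
.physician_days <- function(ph, dates_work, dates_off, cfg) {
  qa <- cfg$idle_cutoff
  sched <- cfg$schedule
  runs_all <- list(); truth_all <- list()
  for (d in seq_along(dates_work)) {
    date <- dates_work[d]
    sh <- .shifts_on(date, sched)
    shift_windows <- tibble(w0 = sh$shift_start + 2, w1 = sh$shift_end - 2)
    total <- max(ph$inbox_total * exp(stats::rnorm(1, 0, cfg$day_total_cv) -
                                        cfg$day_total_cv^2 / 2), 0)
    # day-level wobble of the split in alr space around physician truth
    y1 <- log(max(ph$p_in, 1e-4) / max(ph$p_contig, 1e-4)) +
      stats::rnorm(1, 0, cfg$day_alr_sd)
    y2 <- log(max(ph$p_noncontig, 1e-4) / max(ph$p_contig, 1e-4)) +
      stats::rnorm(1, 0, cfg$day_alr_sd)
    den <- 1 + exp(y1) + exp(y2)
    t_in <- total * exp(y1) / den
    t_nc <- total * exp(y2) / den
    t_cg <- total / den
    batched_day <- stats::runif(1) < ifelse(ph$batcher, 0.85, 0.05)
    # inbox runs: batched days concentrate work in few long blocks
    mean_in <- if (batched_day) max(t_in / 2, 12) else 10
    min_in <- if (batched_day) 1 else 4
    r_in <- .place_runs(.split_runs(t_in, qa, mean_in, min_in),
                        shift_windows, 16)
    cg_windows <- if (stats::runif(1) < 0.8) {
      tibble(w0 = max(sh$shift_end) + 2, w1 = max(sh$shift_end) + 57)
    } else {
      tibble(w0 = min(sh$shift_start) - 57, w1 = min(sh$shift_start) - 2)
    }
    mean_cg <- if (batched_day) max(t_cg, 8) else 9
    r_cg <- .place_runs(.split_runs(t_cg, qa, mean_cg), cg_windows, 16)
    nc_windows <- if (stats::runif(1) < 0.8) {
      tibble(w0 = 1200, w1 = 1375)
    } else {
      tibble(w0 = 335, w1 = 420)
    }
    mean_nc <- if (batched_day) max(t_nc, 10) else 10
    r_nc <- .place_runs(.split_runs(t_nc, qa, mean_nc), nc_windows, 16)
    # non-inbox EHR work, mostly in clinic hours
    e_tot <- max(ph$noninbox_ehr * exp(stats::rnorm(1, 0, 0.12) - 0.0072), 15)
    r_oth <- .place_runs(.split_runs(e_tot * 0.9, qa, 18), shift_windows, 16)
    r_oth2 <- .place_runs(.split_runs(e_tot * 0.1, qa, 10),
                          tibble(w0 = max(sh$shift_end) + 60,
                                 w1 = max(sh$shift_end) + 115), 16)
    day_runs <- bind_rows(
      r_in |> mutate(category = "INBOX"),
      r_cg |> mutate(category = "INBOX"),
      r_nc |> mutate(category = "INBOX"),
      bind_rows(r_oth, r_oth2) |> mutate(category = "OTHER_EHR"))
    day_runs <- .resolve_collisions(day_runs)
    day_runs$physician_id <- ph$physician_id
    day_runs$date <- date
    runs_all[[length(runs_all) + 1]] <- day_runs
    inbox_runs <- day_runs[day_runs$category == "INBOX", ]
    truth_all[[length(truth_all) + 1]] <- tibble(
      physician_id = ph$physician_id, date = date, workday = TRUE,
      batched_day = batched_day,
      inbox_min = sum(inbox_runs$len),
      ehr_min = sum(day_runs$len),
      target_in = t_in, target_contig = t_cg, target_noncontig = t_nc)
  }
  for (date in as.list(dates_off)) {
    nb <- max(ph$nonworkday_inbox * exp(stats::rnorm(1, 0, 0.3) - 0.045), 0)
    oth <- max(stats::rnorm(1, 10, 12), 0)
    win <- tibble(w0 = 540, w1 = 1260)
    r_in <- .place_runs(.split_runs(nb, qa, 9), win, 16)
    r_oth <- .place_runs(.split_runs(oth, qa, 10), win, 16)
    day_runs <- bind_rows(r_in |> mutate(category = "INBOX"),
                          r_oth |> mutate(category = "OTHER_EHR"))
    day_runs <- .resolve_collisions(day_runs)
    day_runs$physician_id <- ph$physician_id
    day_runs$date <- date
    runs_all[[length(runs_all) + 1]] <- day_runs
    truth_all[[length(truth_all) + 1]] <- tibble(
      physician_id = ph$physician_id, date = date, workday = FALSE,
      batched_day = NA,
      inbox_min = sum(day_runs$len[day_runs$category == "INBOX"]),
      ehr_min = sum(day_runs$len),
      target_in = 0, target_contig = 0, target_noncontig = 0)
  }
  list(runs = list_rbind(runs_all), truth = list_rbind(truth_all))
}

# runs from different buckets share windows; push overlapping runs apart
# (keeping >= 2 min between runs so the idle cutoff closes each one)
.resolve_collisions <- function(runs) {
  if (nrow(runs) < 2) return(runs)
  runs <- runs[order(runs$start), ]
  for (i in 2:nrow(runs)) {
    prev_end <- runs$start[i - 1] + runs$len[i - 1]
    if (runs$start[i] < prev_end + 2) runs$start[i] <- prev_end + 2
  }
  runs
}

# turn activity runs into timestamped log events; each run emits events
# over [start, start + len - cutoff] so last-event-carried-forward
# attributes exactly `len` minutes
.emit_events <- function(runs, phys, cfg) {
  qa <- cfg$idle_cutoff
  steps <- ifelse(runs$category == "INBOX",
                  1 / (cfg$inbox_events_per_min %||% cfg$events_per_min),
                  1 / cfg$events_per_min)
  offsets <- purrr::map(seq_len(nrow(runs)), function(i) {
    span <- runs$len[i] - qa
    if (span <= 1e-9) return(0)
    unique(c(seq(0, span, by = steps[i]), span))
  })
  n_ev <- lengths(offsets)
  idx <- rep(seq_len(nrow(runs)), n_ev)
  ev <- tibble(physician_id = runs$physician_id[idx],
               date = runs$date[idx],
               minute = runs$start[idx] + unlist(offsets),
               category = runs$category[idx])
  ev$timestamp <- .midnight(ev$date) + round(ev$minute * 60)
  ev <- ev |> arrange(.data$physician_id, .data$timestamp)

  ph_idx <- match(ev$physician_id, phys$physician_id)
  mix <- as.matrix(phys[, c("mix_patient", "mix_result", "mix_request",
                            "mix_admin")])
  types <- c("PATIENT", "RESULT", "REQUEST", "ADMIN")
  u <- stats::runif(nrow(ev))
  cum <- t(apply(mix, 1, cumsum))
  pick <- 1L + (u > cum[ph_idx, 1]) + (u > cum[ph_idx, 2]) + (u > cum[ph_idx, 3])
  ev$message_type <- ifelse(ev$category == "INBOX", types[pick], "NONE")

  # window switching: per-day switch probability scaled so switches per
  # EHR minute hit the target despite idle tails carrying no events
  ev <- ev |>
    group_by(.data$physician_id, .data$date) |>
    mutate(.n = dplyr::n()) |>
    ungroup()
  day_min <- runs |>
    group_by(.data$physician_id, .data$date) |>
    summarise(total = sum(.data$len), .groups = "drop")
  ev <- ev |> left_join(day_min, by = c("physician_id", "date"))
  p_switch <- pmin(cfg$switch_rate * ev$total / pmax(ev$.n - 1, 1), 1)
  sw <- stats::rbinom(nrow(ev), 1, p_switch)
  ev <- ev |>
    group_by(.data$physician_id) |>
    mutate(first = dplyr::row_number() == 1) |>
    ungroup()
  sw[ev$first] <- 0L
  wid <- cumsum(c(1L, sw[-1]))
  ev$window_id <- sprintf("w%06d", wid)

  # task completions: the day's handled messages are emitted as dedicated
  # zero-duration marker events at sampled inbox-event timestamps (a
  # zero-gap event attributes no extra time, so minute conservation holds)
  tpm <- phys$tpm[ph_idx]
  inbox_day_min <- runs |>
    filter(.data$category == "INBOX") |>
    group_by(.data$physician_id, .data$date) |>
    summarise(inbox = sum(.data$len), .groups = "drop")
  ev <- ev |> left_join(inbox_day_min, by = c("physician_id", "date")) |>
    mutate(inbox = coalesce(.data$inbox, 0))
  n_msg <- round(ev$inbox / tpm)
  ev$is_task_completion <- FALSE
  is_inbox <- which(ev$category == "INBOX")
  key <- paste(ev$physician_id, ev$date)
  host_rows <- unlist(lapply(split(is_inbox, key[is_inbox]), function(rows) {
    m <- n_msg[rows[1]]
    if (m <= 0) return(integer(0))
    sort(sample(rows, m, replace = TRUE))
  }), use.names = FALSE)
  tasks <- ev[host_rows, ]
  tasks$is_task_completion <- TRUE

  bind_rows(ev, tasks) |>
    select("timestamp", "physician_id", "category", "message_type",
           "window_id", "is_task_completion") |>
    arrange(.data$physician_id, .data$timestamp)
}

# wearable stress series: 3-minute samples on a midnight-anchored grid,
# score = group baseline + calibrated 3-wave + physician intercept +
# noise, with device-off runs (samples missing) and activity runs
# (flagged invalid)
.emit_stress <- function(phys, dates, cfg, stress_cal) {
  grid <- seq(0, 1437, by = 3)
  tday <- (grid + 1.5) / 60
  wave <- stress_cal$amplitude * .stress_wave(tday)
  out <- purrr::map(seq_len(nrow(phys)), function(i) {
    ph <- phys[i, ]
    purrr::map(as.list(dates), function(date) {
      mu <- ph$stress_base + wave + ph$stress_u
      score <- pmin(pmax(round(mu + stats::rnorm(length(grid),
                                                 0, cfg$stress_sigma_e)), 0), 100)
      keep <- rep(TRUE, length(grid))
      activity <- rep(FALSE, length(grid))
      dp <- cfg$dropout
      if (!is.null(dp)) {
        if (isTRUE(dp$night_off)) {
          on_at <- stats::rnorm(1, 405, 25)    # ~6:45
          off_at <- stats::rnorm(1, 1410, 20)  # ~23:30
          keep <- keep & grid >= on_at & grid < off_at
        }
        gaps <- bind_rows(
          .random_runs(dp$short_rate, dp$short_mean, 390, 1410),
          .random_runs(dp$long_rate, dp$long_mean, 420, 1380))
        for (r in seq_len(nrow(gaps))) {
          keep <- keep & !(grid >= gaps$s[r] & grid < gaps$e[r])
        }
        act <- .random_runs(dp$activity_rate, dp$activity_mean, 400, 1320)
        for (r in seq_len(nrow(act))) {
          activity <- activity | (grid >= act$s[r] & grid < act$e[r])
        }
      }
      tibble(physician_id = ph$physician_id,
             timestamp = .midnight(date) + grid[keep] * 60,
             score = as.integer(score[keep]),
             activity_flag = activity[keep])
    }) |> list_rbind()
  }) |> list_rbind()
  out |> arrange(.data$physician_id, .data$timestamp)
}

# contiguous episodes (device off or physical activity) within a window
.random_runs <- function(rate, mean_len, lo, hi) {
  n <- stats::rpois(1, rate)
  if (n == 0) return(tibble(s = numeric(0), e = numeric(0)))
  s <- stats::runif(n, lo, hi)
  len <- stats::rgamma(n, shape = 2, scale = mean_len / 2)
  tibble(s = s, e = pmin(s + len, hi))
}

#' @export
print.inbox_cohort <- function(x, ...) {
  cat(sprintf("<inbox_cohort> %d physicians, %d log events, %d stress samples\n",
              nrow(x$roster), nrow(x$events), nrow(x$stress)))
  invisible(x)
}

#' Ground-truth manifest of a synthetic cohort
#'
#' Collects the generator's ground truth in a JSON-serializable form: the
#' group label and behavioural parameters of every physician, realized
#' per-day inbox and EHR minutes (which the pipeline should recover
#' exactly), and the stress-model calibration. This is the oracle all
#' recovery tests compare against.
#'
#' @param cohort an `inbox_cohort` from [generate_cohort()]
#' @param path optional path to also write the manifest as JSON
#' @return list (invisibly written to `path` when given)
#' @export
truth_manifest <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "inbox_cohort"))
  man <- list(
    n_physicians = nrow(cohort$roster),
    group_sizes = as.integer(cohort$config$group_sizes),
    seed = cohort$config$seed,
    physicians = cohort$truth$physicians |>
      select("physician_id", "group", "p_in", "p_noncontig", "p_contig",
             "inbox_total", "tpm", "batcher"),
    days = cohort$truth$days,
    totals = list(inbox_min = sum(cohort$truth$days$inbox_min),
                  ehr_min = sum(cohort$truth$days$ehr_min)),
    stress_calibration = cohort$truth$stress_calibration)
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(man)
}

#' Write a cohort's data streams to plain-text files
#'
#' Emits `events.csv`, `stress.csv`, `roster.csv` and `truth.json` in the
#' formats the package readers consume.
#'
#' @param cohort an `inbox_cohort`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- cohort$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  st <- cohort$stress
  st$timestamp <- format(st$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(st, file.path(dir, "stress.csv"), row.names = FALSE)
  utils::write.csv(cohort$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE)
  truth_manifest(cohort, file.path(dir, "truth.json"))
  invisible(dir)
}
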