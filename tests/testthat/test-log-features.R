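test_that("sessionize attributes inter-event time up to the idle cutoff", {
  ev <- make_events(c("09:00", "09:02"))
  iv <- sessionize(ev)
  expect_equal(iv$minutes, c(2, 5))
  expect_equal(sum(iv$minutes[iv$category == "INBOX"]), 7)

  single <- sessionize(make_events("09:00"))
  expect_equal(single$minutes, 5)

  expect_equal(nrow(sessionize(make_events(character(0)))), 0)

  unsorted <- make_events(c("09:05", "09:00"))
  expect_error(sessionize(unsorted), "sorted")
})

test_that("sessionized minutes match a per-second brute-force scan", {
  set.seed(42)
  for (rep in 1:5) {
    gaps <- sample(c(10, 30, 60, 120, 400, 900), 100, replace = TRUE)
    times <- ts_at("08:00") + cumsum(gaps)
    iv <- sessionize(make_events(times))
    expect_equal(sum(iv$minutes), brute_force_attributed(times),
                 tolerance = 1e-8)
  }
})

test_that("longer idle cutoffs never attribute less time", {
  set.seed(1)
  times <- ts_at("08:00") + cumsum(sample(30:600, 50, replace = TRUE))
  totals <- vapply(c(1, 3, 5, 10, 30),
                   function(k) sum(sessionize(make_events(times), k)$minutes),
                   numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("hourly binning splits straddling intervals and conserves minutes", {
  iv <- make_intervals("09:25", 10)
  binned <- bin_hourly(iv, bin_anchor = 30)
  expect_equal(nrow(binned), 2)
  expect_equal(sort(binned$minutes), c(5, 5))
  expect_equal(format(binned$bin_start, "%H:%M"), c("08:30", "09:30"))

  expect_equal(nrow(bin_hourly(make_intervals(character(0), numeric(0)))), 0)

  # an interval starting exactly on a bin boundary belongs to the later bin
  edge <- bin_hourly(make_intervals("09:30", 10), bin_anchor = 30)
  expect_equal(format(edge$bin_start, "%H:%M"), "09:30")

  set.seed(3)
  gaps <- runif(40, 1, 40)
  mins <- runif(40, 0.5, 150)
  start_min <- 300 + cumsum(c(0, (mins + gaps)[-40]))
  iv <- make_intervals(rep("00:00", 40), mins)
  iv$start <- ts_at("00:00") + start_min * 60
  iv$end <- iv$start + mins * 60
  rnd <- bin_hourly(iv)
  expect_equal(sum(rnd$minutes), sum(mins), tolerance = 1e-6)
  per_bin <- dplyr::count(rnd, bin_start, wt = minutes)
  expect_true(all(per_bin$n <= 60 + 1e-9))
})

test_that("window switches are adjacent window-id changes", {
  ev <- make_events(c("09:00", "09:01", "09:02", "09:03"),
                    window_id = c("A", "A", "B", "A"))
  expect_equal(sum(count_window_switches(ev)$n_window_switches), 2)

  same <- make_events(c("09:00", "09:01", "09:02"), window_id = "A")
  expect_equal(sum(count_window_switches(same)$n_window_switches), 0)

  set.seed(11)
  ids <- sample(letters[1:4], 500, replace = TRUE)
  ev <- make_events(ts_at("08:00") + seq_len(500) * 20, window_id = ids)
  oracle <- sum(ids[-1] != ids[-length(ids)])
  expect_equal(sum(count_window_switches(ev)$n_window_switches), oracle)
})

test_that("switching rate is switches per EHR minute, missing without EHR time", {
  hourly <- tibble::tibble(
    physician_id = "p1", date = as.Date("2023-03-06"),
    bin_start = ts_at(c("09:30", "10:30")),
    minutes_ehr = c(20, 10), minutes_inbox = c(5, 5),
    minutes_patient = c(5, 5), minutes_result = 0, minutes_request = 0,
    minutes_admin = 0, n_tasks = c(10, 5), n_window_switches = c(90, 30))
  expect_equal(switching_rate(hourly)$switch_rate, 4)

  zero <- dplyr::mutate(hourly, minutes_ehr = 0, n_window_switches = 0)
  expect_true(is.na(switching_rate(zero)$switch_rate))
})

test_that("time per message divides inbox minutes by completed tasks", {
  hourly <- tibble::tibble(
    physician_id = "p1", date = as.Date("2023-03-06"),
    bin_start = ts_at("09:30"),
    minutes_ehr = 60, minutes_inbox = 46, minutes_patient = 46,
    minutes_result = 0, minutes_request = 0, minutes_admin = 0,
    n_tasks = 100, n_window_switches = 0)
  expect_equal(time_per_message(hourly)$time_per_message, 0.46)
  expect_equal(
    time_per_message(dplyr::mutate(hourly, minutes_inbox = 35))$time_per_message,
    0.35)
  expect_true(is.na(
    time_per_message(dplyr::mutate(hourly, n_tasks = 0))$time_per_message))
})

test_that("hourly usage conserves sessionized time and type minutes sum to inbox", {
  set.seed(8)
  times <- ts_at("08:00") + cumsum(sample(20:500, 200, replace = TRUE))
  cat <- sample(c("INBOX", "OTHER_EHR"), 200, replace = TRUE)
  ev <- make_events(times, category = cat,
                    message_type = ifelse(cat == "INBOX",
                                          sample(c("PATIENT", "RESULT",
                                                   "REQUEST", "ADMIN"),
                                                 200, TRUE), "NONE"),
                    window_id = sample(letters[1:5], 200, TRUE))
  usage <- hourly_usage(ev)
  iv <- sessionize(ev)
  expect_equal(sum(usage$minutes_ehr), sum(iv$minutes), tolerance = 1e-6)
  expect_equal(usage$minutes_inbox,
               usage$minutes_patient + usage$minutes_result +
                 usage$minutes_request + usage$minutes_admin,
               tolerance = 1e-6)
  expect_true(all(usage$minutes_inbox <= usage$minutes_ehr + 1e-9))
})

test_that("events violating the schema are rejected", {
  ev <- make_events("09:00")
  bad <- dplyr::mutate(ev, message_type = "NONE")  # INBOX must carry a type
  expect_error(sessionize(bad), "message_type")
  bad2 <- dplyr::mutate(ev, category = "PORTAL")
  expect_error(sessionize(bad2), "category")
})
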