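test_that("hourly stress classifies 3-minute samples by score band", {
  h <- hourly_stress(make_samples(rep(60, 20)))
  expect_equal(h$valid_minutes, 60)
  expect_equal(h$stress_minutes, 60)
  expect_equal(h$stress_fraction, 1)

  h <- hourly_stress(make_samples(c(rep(70, 4), rep(30, 6))))
  expect_equal(h$valid_minutes, 30)
  expect_equal(h$stress_minutes, 12)
  expect_equal(h$stress_fraction, 0.4)

  # low-band scores (25-50) and rest (<25) are valid but not stress
  h <- hourly_stress(make_samples(c(40, 20, 51, 50)))
  expect_equal(h$valid_minutes, 12)
  expect_equal(h$stress_minutes, 3)
})

test_that("activity-flagged and missing samples carry no valid minutes", {
  s <- make_samples(c(60, 60, NA, 60))
  s$activity_flag[2] <- TRUE
  h <- hourly_stress(s)
  expect_equal(h$valid_minutes, 6)
  expect_equal(h$stress_minutes, 6)
})

test_that("hourly stress matches a per-minute brute-force classification", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 120
    keep <- runif(n) > 0.3
    s <- make_samples(sample(0:100, n, TRUE), from = "06:00")[keep, ]
    s$activity_flag <- runif(nrow(s)) < 0.15
    h <- hourly_stress(s)
    # oracle: classify each minute of the day by its covering sample
    mins <- tibble::tibble(
      minute = rep(as.numeric(difftime(s$timestamp, ts_at("00:00"),
                                       units = "mins")), each = 3) +
        rep(0:2, nrow(s)),
      valid = rep(!s$activity_flag & !is.na(s$score), each = 3),
      stress = rep(!s$activity_flag & !is.na(s$score) &
                     dplyr::coalesce(s$score > 50, FALSE), each = 3))
    mins$bin <- floor((mins$minute - 30) / 60)
    oracle <- dplyr::summarise(dplyr::group_by(mins, bin),
                               valid = sum(valid), stress = sum(stress))
    oracle <- oracle[oracle$valid > 0, ]
    got <- h[order(h$bin_start), ]
    expect_equal(got$valid_minutes, oracle$valid)
    expect_equal(got$stress_minutes, oracle$stress)
  }
})

test_that("stress fractions reproduce whole-percent arithmetic", {
  expect_equal(stress_fraction(80, 243), 33)
  expect_equal(stress_fraction(47, 265), 18)
  expect_equal(stress_fraction(0, 100), 0)
  expect_true(is.na(stress_fraction(5, 0)))
  expect_equal(stress_fraction(1, 3, digits = NULL), 100 / 3)
})

test_that("validity filters remove short hours and days with a full report", {
  hours <- tibble::tibble(
    physician_id = "p1", date = as.Date("2023-03-06"),
    bin_start = ts_at("00:30") + (0:9) * 3600,
    valid_minutes = c(60, 19.9, 20, 5, 45, 60, 0, 21, 60, 10),
    stress_minutes = 0, stress_fraction = 0)
  days <- tibble::tibble(
    physician_id = "p1",
    date = as.Date("2023-03-06") + 0:3,
    valid_minutes = c(300, 119, 200, 500),
    stress_minutes = 0, stress_fraction = 0,
    workday = c(TRUE, TRUE, FALSE, TRUE),
    inbox_minutes = c(30, 10, 5, 0))
  f <- apply_validity_filters(hours, days)
  expect_equal(nrow(f$hours), 6)
  expect_equal(f$report$n_removed, c(4, 1, 1, 1))
  expect_equal(f$report$n_input, c(10, 4, 3, 2))
  expect_equal(nrow(f$days), 1)
  # input = retained + removed; day stages chain
  expect_equal(f$report$n_input - f$report$n_removed, c(6, 3, 2, 1))
  expect_equal(f$report$n_input[3:4],
               (f$report$n_input - f$report$n_removed)[2:3])

  # idempotence: filtering retained records again removes nothing
  f2 <- apply_validity_filters(f$hours,
                               dplyr::mutate(f$days, workday = TRUE))
  expect_equal(f2$report$n_removed, rep(0L, 4))
})

test_that("filter removal counts match a brute-force filter on random dropout", {
  set.seed(6)
  hours <- tibble::tibble(
    physician_id = sample(c("a", "b"), 300, TRUE),
    date = as.Date("2023-03-06"),
    bin_start = ts_at("00:30") + sample(0:1000, 300) * 3600,
    valid_minutes = runif(300, 0, 60),
    stress_minutes = 0, stress_fraction = 0)
  f <- apply_validity_filters(hours)
  expect_equal(f$report$n_removed[1], sum(hours$valid_minutes < 20))
  expect_equal(nrow(f$hours), sum(hours$valid_minutes >= 20))
})

test_that("the daily stress curve averages physician-hours per clock bin", {
  h1 <- hourly_stress(make_samples(rep(60, 20) * rep(c(1, 0.5), each = 10)))
  # one physician, constant 30% fraction across two identical-shape hours
  hours <- tibble::tibble(
    physician_id = "p1", date = as.Date("2023-03-06") + 0:1,
    bin_start = ts_at("09:30", c("2023-03-06", "2023-03-07")),
    valid_minutes = 60, stress_minutes = 18, stress_fraction = 0.3)
  cv <- daily_stress_curve(hours)
  expect_equal(cv$mean_fraction, 0.3)
  expect_equal(cv$sd_fraction, 0)

  # two physicians at 0.2 and 0.4: mean 30%, SD = sd(c(.2,.4))
  hours2 <- tibble::tibble(
    physician_id = c("p1", "p2"), date = as.Date("2023-03-06"),
    bin_start = ts_at("09:30"),
    valid_minutes = 60, stress_minutes = c(12, 24),
    stress_fraction = c(0.2, 0.4))
  cv2 <- daily_stress_curve(hours2)
  expect_equal(cv2$mean_fraction, 0.3)
  expect_equal(cv2$sd_fraction, sd(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(cv2$se_fraction, sd(c(0.2, 0.4)) / sqrt(2), tolerance = 1e-12)
})

test_that("work-hours stress sums only shift-intersecting hour bins", {
  hours <- tibble::tibble(
    physician_id = "p1", date = as.Date("2023-03-06"),
    bin_start = ts_at(c("08:30", "12:30", "13:30", "20:30")),
    valid_minutes = c(60, 60, 60, 60), stress_minutes = c(30, 15, 12, 60),
    stress_fraction = c(0.5, 0.25, 0.2, 1))
  ws <- work_hours_stress(hours)
  # the 12:30-13:30 lunch bin and the evening bin are excluded; the first
  # morning and first afternoon bins count
  expect_equal(ws$work_valid_minutes, 120)
  expect_equal(ws$work_stress_minutes, 42)
})

test_that("stress minutes never exceed valid minutes on generated data", {
  set.seed(2)
  s <- make_samples(sample(0:100, 200, TRUE), from = "05:00")
  h <- hourly_stress(s)
  expect_true(all(h$stress_minutes <= h$valid_minutes + 1e-9))
  expect_true(all(h$stress_fraction >= 0 & h$stress_fraction <= 1))
  d <- daily_stress(h)
  expect_true(all(d$stress_minutes <= d$valid_minutes + 1e-9))
})
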