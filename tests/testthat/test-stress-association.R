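test_that("the model frame centers covariates and reports VIFs", {
  sim <- simulate_stress_days(n_physicians = 10, days_per = 5, seed = 1)
  fr <- build_model_frame(sim)
  for (v in c("switch_rate", "inbox_work_min", "after_prop")) {
    expect_equal(mean(fr[[v]]), 0, tolerance = 1e-10)
    expect_equal(fr[[v]] + mean(fr[[paste0(v, "_raw")]]),
                 fr[[paste0(v, "_raw")]], tolerance = 1e-10)
  }
  expect_false(is.null(attr(fr, "vif")))
  expect_true(all(attr(fr, "vif") < 5))

  single <- build_model_frame(sim[1, ])
  expect_equal(single$switch_rate, 0)

  # a duplicated covariate inflates VIF
  dup <- sim
  dup$noninbox_work_min <- dup$inbox_work_min * 1.001 + rnorm(nrow(dup), 0, 0.01)
  frd <- build_model_frame(dup)
  expect_true(any(attr(frd, "vif") > 5))

  const <- sim
  const$patient_prop <- 0.37
  expect_warning(build_model_frame(const), "zero-variance")
})

test_that("known coefficients are recovered within 2 standard errors", {
  beta <- c(intercept = -1.7, switch_rate = 0.1, inbox_work_min = 0.003,
            after_prop = 0.35, batched = 0.13)
  sim <- simulate_stress_days(n_physicians = 40, days_per = 5, beta = beta,
                              sigma_u = 0.5, seed = 21)
  fit <- fit_poisson_mixed(build_model_frame(sim),
                           stress_minutes ~ switch_rate + inbox_work_min +
                             after_prop + batched + (1 | physician_id))
  td <- tidy(fit)
  for (v in setdiff(names(beta), "intercept")) {
    row <- td[td$term == v, ]
    expect_lt(abs(row$estimate - beta[[v]]), 2 * row$std_error)
  }
  expect_true(fit$converged)
})

test_that("doubling the exposure window leaves rate estimates unchanged", {
  sim <- simulate_stress_days(n_physicians = 20, days_per = 5, seed = 3)
  f1 <- fit_poisson_mixed(build_model_frame(sim),
                          stress_minutes ~ inbox_work_min + batched +
                            (1 | physician_id))
  sim2 <- sim
  sim2$work_valid_minutes <- sim2$work_valid_minutes * 2
  f2 <- fit_poisson_mixed(build_model_frame(sim2),
                          stress_minutes ~ inbox_work_min + batched +
                            (1 | physician_id))
  slopes <- function(f) tidy(f)$estimate[tidy(f)$term != "(Intercept)"]
  expect_equal(slopes(f1), slopes(f2), tolerance = 1e-6)
})

test_that("conditional R2 is never below marginal R2", {
  for (s in 1:5) {
    sim <- simulate_stress_days(n_physicians = 15, days_per = 4, seed = 30 + s)
    fit <- fit_poisson_mixed(build_model_frame(sim),
                             stress_minutes ~ inbox_work_min + batched +
                               (1 | physician_id))
    expect_gte(fit$conditional_r2, fit$marginal_r2)
    expect_true(fit$marginal_r2 >= 0 && fit$conditional_r2 <= 1)
  }
})

test_that("centering does not change slopes, only the intercept", {
  sim <- simulate_stress_days(n_physicians = 20, days_per = 5, seed = 4)
  fr_centered <- build_model_frame(sim)
  fr_raw <- sim
  fr_raw$stress_minutes <- as.integer(round(fr_raw$work_stress_minutes))
  fr_raw$valid_minutes <- fr_raw$work_valid_minutes
  f1 <- fit_poisson_mixed(fr_centered,
                          stress_minutes ~ inbox_work_min + (1 | physician_id))
  f2 <- fit_poisson_mixed(fr_raw,
                          stress_minutes ~ inbox_work_min + (1 | physician_id))
  s1 <- tidy(f1); s2 <- tidy(f2)
  expect_equal(s1$estimate[s1$term == "inbox_work_min"],
               s2$estimate[s2$term == "inbox_work_min"], tolerance = 1e-4)
  shift <- s2$estimate[s2$term == "(Intercept)"] +
    mean(sim$inbox_work_min) * s2$estimate[s2$term == "inbox_work_min"]
  expect_equal(s1$estimate[s1$term == "(Intercept)"], shift, tolerance = 1e-3)
})

test_that("standardized coefficients scale slopes by covariate SDs", {
  sim <- simulate_stress_days(n_physicians = 20, days_per = 5, seed = 5)
  fr <- build_model_frame(sim)
  fit <- fit_poisson_mixed(fr, stress_minutes ~ inbox_work_min +
                             (1 | physician_id))
  td <- tidy(fit)
  row <- td[td$term == "inbox_work_min", ]
  expect_equal(unname(row$std_estimate),
               unname(row$estimate * sd(fr$inbox_work_min)),
               tolerance = 1e-10)
  expect_true(is.na(td$std_estimate[td$term == "(Intercept)"]))
})

test_that("model comparison prefers the generating model by AIC", {
  beta <- c(intercept = -1.7, inbox_work_min = 0.006, batched = 0.25)
  sim <- simulate_stress_days(n_physicians = 40, days_per = 5, beta = beta,
                              sigma_u = 0.5, seed = 6)
  fr <- build_model_frame(sim)
  cmp <- compare_models(fr, list(
    base = stress_minutes ~ 1 + (1 | physician_id),
    full = stress_minutes ~ inbox_work_min + batched + (1 | physician_id)))
  expect_equal(cmp$report$model[cmp$report$chosen], "full")
  expect_lt(cmp$report$aic[cmp$report$model == "full"],
            cmp$report$aic[cmp$report$model == "base"])

  # against pure-noise covariates the generating model usually wins
  set.seed(60)
  wins <- vapply(1:25, function(i) {
    d <- simulate_stress_days(30, 5, beta = beta, sigma_u = 0.5,
                              seed = 600 + i)
    d$noise1 <- rnorm(nrow(d)); d$noise2 <- rnorm(nrow(d))
    f <- build_model_frame(d)
    rep <- compare_models(f, list(
      true = stress_minutes ~ inbox_work_min + batched + (1 | physician_id),
      noisy = stress_minutes ~ inbox_work_min + batched + noise1 + noise2 +
        (1 | physician_id)))$report
    rep$model[rep$chosen] == "true"
  }, logical(1))
  expect_gte(mean(wins), 0.7)
})
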