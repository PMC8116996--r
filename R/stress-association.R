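#' Assemble the physician-day model frame
#'
#' Joins daily usage covariates, temporal splits, batching flags, roster
#' demographics and work-hours stress outcomes into one row per retained
#' physician-day, the unit of analysis for the stress association model.
#' Continuous covariates are mean-centered (centering leaves slopes
#' unchanged and makes the intercept interpretable at average exposure);
#' raw values are kept alongside with a `_raw` suffix. Weekday enters as a
#' factor with Friday as the reference level. Variance inflation factors
#' for the fixed-effect design are attached as `attr(frame, "vif")`;
#' zero-variance covariates are dropped with a warning.
#'
#' @param days tibble with one row per physician-day carrying
#'   `physician_id`, `date`, the outcome `work_stress_minutes`, the
#'   exposure `work_valid_minutes`, and covariates `switch_rate`,
#'   `inbox_work_min`, `noninbox_work_min`, `after_prop`, `patient_prop`,
#'   `batched`, plus roster columns `fte`, `age`, `sex`
#' @param center continuous covariates to center (defaults to all standard
#'   model covariates present)
#' @return tibble of class `physician_day_frame`
#' @export
build_model_frame <- function(days,
                              center = c("fte", "age", "switch_rate",
                                         "inbox_work_min", "noninbox_work_min",
                                         "after_prop", "patient_prop")) {
  need <- c("physician_id", "date", "work_stress_minutes", "work_valid_minutes")
  missing <- setdiff(need, names(days))
  if (length(missing) > 0) {
    abort(paste("days missing columns:", paste(missing, collapse = ", ")))
  }
  frame <- days |>
    mutate(stress_minutes = as.integer(round(.data$work_stress_minutes)),
           valid_minutes = .data$work_valid_minutes,
           weekday = factor(.wday_abb(.data$date),
                            levels = c("Fri", "Mon", "Tue", "Wed", "Thu")))
  if ("sex" %in% names(frame) && is.character(frame$sex)) {
    # female indicator reported against a male reference
    frame$sex <- factor(frame$sex, levels = c("M", "F"))
  }
  center <- intersect(center, names(frame))
  dropped <- character()
  for (v in center) {
    if (isTRUE(sd(frame[[v]], na.rm = TRUE) == 0)) {
      dropped <- c(dropped, v)
      next
    }
    frame[[paste0(v, "_raw")]] <- frame[[v]]
    frame[[v]] <- frame[[v]] - mean(frame[[v]], na.rm = TRUE)
  }
  if (length(dropped) > 0) {
    warn(paste("zero-variance covariates dropped:",
               paste(dropped, collapse = ", ")))
    frame <- frame |> select(-dplyr::all_of(dropped))
  }
  kept <- setdiff(center, dropped)
  vif <- NULL
  if (length(kept) >= 2 && nrow(frame) > length(kept) + 2) {
    fml <- stats::as.formula(paste("stress_minutes ~",
                                   paste(kept, collapse = " + ")))
    vif <- tryCatch(car::vif(stats::lm(fml, data = frame)),
                    error = function(e) NULL)
  }
  attr(frame, "vif") <- vif
  class(frame) <- c("physician_day_frame", class(frame))
  frame
}

.default_formula <- function(frame) {
  covs <- intersect(c("fte", "age", "sex", "switch_rate", "inbox_work_min",
                      "noninbox_work_min", "after_prop", "patient_prop",
                      "batched", "weekday"), names(frame))
  stats::as.formula(paste("stress_minutes ~", paste(covs, collapse = " + "),
                          "+ (1 | physician_id)"))
}

#' Fit the Poisson mixed-effects stress model
#'
#' Work-hours stress minutes are modelled as counts accumulating over the
#' valid HRV measurement window: a log-link Poisson generalized linear
#' mixed model with `log(valid_minutes)` as exposure offset (so fixed
#' effects describe stress *rates*) and a random intercept per physician
#' absorbing stable individual differences in physiologic stress.
#' Estimation is by Laplace-approximate maximum likelihood
#' ([lme4::glmer()]).
#'
#' Reported alongside the coefficients: standardized coefficients
#' (each slope multiplied by the sample SD of its design column) and
#' marginal/conditional R-squared by latent-scale variance partitioning,
#' with the log-normal approximation `ln(1 + 1/lambda)` for the
#' observation-level variance of a Poisson response (`lambda` = mean
#' count). Marginal R2 is the share of latent variance explained by fixed
#' effects alone; conditional R2 adds the random intercept.
#'
#' @param frame output of [build_model_frame()]
#' @param formula model formula; default uses the standard covariate set
#'   present in `frame` plus `(1 | physician_id)`
#' @return object of class `stress_glmm`
#' @export
fit_poisson_mixed <- function(frame, formula = NULL) {
  if (dplyr::n_distinct(frame$physician_id) < 2) {
    abort("need at least 2 physicians for a random-intercept model")
  }
  formula <- formula %||% .default_formula(frame)
  formula <- stats::update(formula, . ~ . + offset(log(valid_minutes)))
  fit <- lme4::glmer(formula, data = frame, family = stats::poisson(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  r2 <- .r2_poisson_glmm(fit, frame)
  co <- summary(fit)$coefficients
  X <- stats::model.matrix(fit)
  sds <- apply(X, 2, sd)
  std <- co[, "Estimate"] * sds[rownames(co)]
  std["(Intercept)"] <- NA_real_
  coef_tab <- tibble(term = rownames(co),
                     estimate = co[, "Estimate"],
                     std_error = co[, "Std. Error"],
                     std_estimate = unname(std),
                     statistic = co[, "z value"],
                     p_value = co[, "Pr(>|z|)"])
  structure(list(fit = fit, coefficients = coef_tab,
                 marginal_r2 = r2[["marginal"]],
                 conditional_r2 = r2[["conditional"]],
                 re_sd = sqrt(r2[["var_random"]]),
                 aic = stats::AIC(fit), converged = conv,
                 n = nrow(frame),
                 n_physicians = dplyr::n_distinct(frame$physician_id),
                 formula = formula),
            class = "stress_glmm")
}

# latent-scale variance partition for a Poisson log-link GLMM
.r2_poisson_glmm <- function(fit, frame) {
  eta_fixed <- as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit))
  var_f <- stats::var(eta_fixed)
  vc <- lme4::VarCorr(fit)
  var_u <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  lambda <- mean(frame$stress_minutes)
  var_e <- log(1 + 1 / max(lambda, 1e-8))
  tot <- var_f + var_u + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_u) / tot,
    var_random = var_u)
}

#' @export
print.stress_glmm <- function(x, ...) {
  cat(sprintf(paste0("<stress_glmm> %d physician-days, %d physicians | ",
                     "AIC %.1f | marginal R2 %.3f, conditional R2 %.3f%s\n"),
              x$n, x$n_physicians, x$aic, x$marginal_r2, x$conditional_r2,
              if (x$converged) "" else " | NOT CONVERGED"))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @export
tidy.stress_glmm <- function(x, ...) x$coefficients

#' @export
glance.stress_glmm <- function(x, ...) {
  tibble(aic = x$aic, marginal_r2 = x$marginal_r2,
         conditional_r2 = x$conditional_r2, re_sd = x$re_sd,
         n = x$n, n_physicians = x$n_physicians, converged = x$converged)
}

#' Compare candidate model formulas by AIC
#'
#' Fits each candidate on the same frame and tabulates AIC and marginal /
#' conditional R2; the lowest-AIC candidate is marked chosen. Candidates
#' that fail to converge are excluded with a note.
#'
#' @param frame output of [build_model_frame()]
#' @param formulas named list of model formulas
#' @return list with `chosen` (a `stress_glmm`) and `report` (tibble)
#' @export
compare_models <- function(frame, formulas) {
  fits <- purrr::imap(formulas, function(f, nm) {
    tryCatch(fit_poisson_mixed(frame, f), error = function(e) NULL)
  })
  report <- purrr::imap(fits, function(f, nm) {
    if (is.null(f)) {
      tibble(model = nm, aic = NA_real_, marginal_r2 = NA_real_,
             conditional_r2 = NA_real_, converged = FALSE,
             note = "failed to fit")
    } else {
      tibble(model = nm, aic = f$aic, marginal_r2 = f$marginal_r2,
             conditional_r2 = f$conditional_r2, converged = f$converged,
             note = "")
    }
  }) |> list_rbind()
  usable <- which(report$converged)
  if (length(usable) == 0) abort("no candidate model converged")
  pick <- usable[which.min(report$aic[usable])]
  report$chosen <- seq_len(nrow(report)) == pick
  list(chosen = fits[[pick]], report = report)
}

#' Simulate physician-day data from a known Poisson mixed model
#'
#' Generates physician-day frames directly from the generative model the
#' association stage assumes: covariates drawn at realistic scales, a
#' physician random intercept, and stress minutes drawn Poisson with a
#' valid-minute exposure offset. Used for parameter-recovery, type-I-error
#' and offset-invariance checks.
#'
#' @param n_physicians,days_per cohort dimensions
#' @param beta named fixed effects on the log-rate scale; names from
#'   `intercept`, `switch_rate`, `inbox_work_min`, `noninbox_work_min`,
#'   `after_prop`, `patient_prop`, `batched`
#' @param sigma_u SD of the physician random intercept
#' @param mean_valid mean valid minutes per day (exposure)
#' @param seed integer seed
#' @return tibble ready for [build_model_frame()] (covariates uncentered),
#'   with the true physician intercepts in `attr(, "truth")`
#' @export
simulate_stress_days <- function(n_physicians = 40, days_per = 5,
                                 beta = c(intercept = -1.7,
                                          inbox_work_min = 0.003,
                                          batched = 0.13),
                                 sigma_u = 0.5, mean_valid = 240, seed = 1) {
  withr::with_seed(seed, {
    n <- n_physicians * days_per
    id <- rep(sprintf("p%02d", seq_len(n_physicians)), each = days_per)
    covs <- tibble(
      physician_id = id,
      date = rep(as.Date("2023-03-06") + rep(0:4, length.out = days_per),
                 n_physicians),
      switch_rate = stats::rnorm(n, 4.25, 0.5),
      inbox_work_min = pmax(stats::rnorm(n, 40, 15), 2),
      noninbox_work_min = pmax(stats::rnorm(n, 145, 30), 10),
      after_prop = pmin(pmax(stats::rnorm(n, 0.3, 0.2), 0), 1),
      patient_prop = pmin(pmax(stats::rnorm(n, 0.37, 0.1), 0), 1),
      batched = stats::rbinom(n, 1, 0.3),
      work_valid_minutes = pmax(round(stats::rnorm(n, mean_valid, 40)), 60))
    u <- stats::rnorm(n_physicians, 0, sigma_u)
    eta <- beta[["intercept"]] + u[match(id, unique(id))]
    for (v in setdiff(names(beta), "intercept")) {
      eta <- eta + beta[[v]] * (covs[[v]] - mean(covs[[v]]))
    }
    covs$work_stress_minutes <- stats::rpois(n, exp(eta + log(covs$work_valid_minutes)))
    # stress cannot exceed the measurement window
    covs$work_stress_minutes <- pmin(covs$work_stress_minutes,
                                     covs$work_valid_minutes)
    attr(covs, "truth") <- list(beta = beta, sigma_u = sigma_u, u = u)
    covs
  })
}
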