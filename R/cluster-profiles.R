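#' Per-physician work-pattern profiles
#'
#' Builds the feature vector that drives clustering: each physician's mean
#' daily temporal split of inbox time (work-hours / contiguous-after /
#' noncontiguous-after proportions), plus auxiliary descriptors (batched-day
#' fraction, time per message, message-type time shares, nonworkday inbox
#' minutes) and roster demographics when supplied. Proportions are averaged
#' over workdays with any inbox time.
#'
#' @param splits output of [split_by_work_hours()] on workday inbox
#'   intervals
#' @param batched output of [is_batched_day()] (optional)
#' @param usage output of [hourly_usage()] (optional; message shares and
#'   time per message are derived from it)
#' @param roster tibble with `physician_id` and demographic columns
#'   (optional)
#' @param nonworkday_inbox tibble `physician_id`, `nonworkday_inbox_min`
#'   (optional)
#' @return tibble, one row per physician
#' @export
physician_profiles <- function(splits, batched = NULL, usage = NULL,
                               roster = NULL, nonworkday_inbox = NULL) {
  prof <- splits |>
    filter(.data$total_inbox_min > 0) |>
    group_by(.data$physician_id) |>
    summarise(p_in_hours = mean(.data$p_in_hours),
              p_contiguous = mean(.data$p_contiguous),
              p_noncontiguous = mean(.data$p_noncontiguous),
              work_inbox_min = mean(.data$in_hours_min),
              after_inbox_min = mean(.data$contiguous_after_min +
                                       .data$noncontiguous_after_min),
              n_days = dplyr::n(), .groups = "drop")
  if (!is.null(batched)) {
    prof <- prof |>
      left_join(batched |>
                  group_by(.data$physician_id) |>
                  summarise(batch_frac = mean(.data$batched), .groups = "drop"),
                by = "physician_id")
  }
  if (!is.null(usage)) {
    # pooled over days: total inbox minutes over total messages handled
    tpm <- usage |>
      group_by(.data$physician_id) |>
      summarise(time_per_message = ifelse(sum(.data$n_tasks) > 0,
                                          sum(.data$minutes_inbox) /
                                            sum(.data$n_tasks), NA_real_),
                .groups = "drop")
    shares <- usage |>
      group_by(.data$physician_id) |>
      summarise(across(c("minutes_patient", "minutes_result",
                         "minutes_request", "minutes_admin", "minutes_inbox"),
                       sum), .groups = "drop") |>
      mutate(share_patient = .data$minutes_patient / .data$minutes_inbox,
             share_result = .data$minutes_result / .data$minutes_inbox,
             share_request = .data$minutes_request / .data$minutes_inbox,
             share_admin = .data$minutes_admin / .data$minutes_inbox) |>
      select("physician_id", dplyr::starts_with("share_"))
    prof <- prof |> left_join(tpm, by = "physician_id") |>
      left_join(shares, by = "physician_id")
  }
  if (!is.null(nonworkday_inbox)) {
    prof <- prof |> left_join(nonworkday_inbox, by = "physician_id")
  }
  if (!is.null(roster)) {
    prof <- prof |> left_join(roster, by = "physician_id")
  }
  prof
}

# additive log-ratio coordinates of the 3-part temporal split, with a small
# floor so zero proportions stay finite
.alr_features <- function(profiles, floor = 0.002) {
  p <- cbind(profiles$p_in_hours, profiles$p_noncontiguous,
             profiles$p_contiguous)
  p <- pmax(p, floor)
  p <- p / rowSums(p)
  cbind(alr1 = log(p[, 1] / p[, 3]), alr2 = log(p[, 2] / p[, 3]))
}

#' Fit a Gaussian-mixture clustering of physician profiles
#'
#' Fits a `K`-component Gaussian mixture to the temporal-split features.
#' Because the three proportions sum to one, the mixture is fitted on the
#' 2-dimensional additive-log-ratio (alr) representation of the simplex; a
#' light conjugate prior regularizes covariances against singularity at
#' small n. Components are mapped to reporting groups by their temporal
#' behaviour: group 1 has the highest mean noncontiguous after-hours
#' share, group 2 the highest work-hours share of the remainder, group 3
#' the rest. The silhouette score is computed on the raw proportion
#' features with Euclidean distance.
#'
#' @param profiles output of [physician_profiles()] (needs the three
#'   proportion columns)
#' @param K number of mixture components (default 3)
#' @param seed integer seed controlling the fit (mixture initialisation)
#' @param n_restarts best-of-n restarts safeguard around the model-based
#'   initialisation (default 1; the hierarchical initialisation is
#'   deterministic)
#' @return object of class `inbox_clusters`: list with `assignments`
#'   (tibble `physician_id`, `cluster`, `group`), `K`, `silhouette`,
#'   `means` (per-group mean proportions), `weights`, `model` (the mclust
#'   fit), `loglik`
#' @export
fit_mixture <- function(profiles, K = 3, seed = 1, n_restarts = 1) {
  if (nrow(profiles) < K + 1) abort("need at least K+1 physicians")
  feats <- .alr_features(profiles)
  if (any(!is.finite(feats))) abort("profile features must be finite")
  fit <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1, n_restarts))) {
      # mclust resolves its own helpers on the search path, so the fit
      # runs with the package temporarily attached
      m <- tryCatch(
        withr::with_package("mclust",
                            Mclust(feats, G = K, prior = priorControl(),
                                   verbose = FALSE),
                            verbose = FALSE),
        error = function(e) NULL)
      if (!is.null(m) && (is.null(best) || m$loglik > best$loglik)) best <- m
    }
    best
  })
  if (is.null(fit)) abort("mixture fit failed for every restart")
  cl <- fit$classification
  sil <- if (K >= 2) {
    p3 <- cbind(profiles$p_in_hours, profiles$p_noncontiguous,
                profiles$p_contiguous)
    mean(cluster::silhouette(cl, stats::dist(p3))[, "sil_width"])
  } else NA_real_
  group_map <- .map_groups(profiles, cl)
  assignments <- tibble(physician_id = profiles$physician_id,
                        cluster = as.integer(cl),
                        group = group_map[as.character(cl)])
  means <- profiles |>
    mutate(group = assignments$group) |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              across(c("p_in_hours", "p_contiguous", "p_noncontiguous"),
                     mean), .groups = "drop")
  structure(list(assignments = assignments, K = K, silhouette = sil,
                 means = means, weights = fit$parameters$pro, model = fit,
                 loglik = fit$loglik),
            class = "inbox_clusters")
}

# mixture components carry arbitrary labels; identify reporting groups by
# behaviour: group 1 = heaviest noncontiguous after-hours share, group 2 =
# most work-hours-dominant of the remainder, group 3+ = the rest by
# descending work-hours share
.map_groups <- function(profiles, cl) {
  stats_tab <- tibble(cl = cl,
                      pnc = profiles$p_noncontiguous,
                      pin = profiles$p_in_hours) |>
    group_by(.data$cl) |>
    summarise(pnc = mean(.data$pnc), pin = mean(.data$pin), .groups = "drop")
  ids <- stats_tab$cl
  g1 <- ids[which.max(stats_tab$pnc)]
  rest <- stats_tab |> filter(.data$cl != g1) |> arrange(dplyr::desc(.data$pin))
  ordered <- c(g1, rest$cl)
  setNames(seq_along(ordered), as.character(ordered))[as.character(ids)] |>
    setNames(as.character(ids))
}

#' @export
print.inbox_clusters <- function(x, ...) {
  cat(sprintf("<inbox_clusters> K = %d, silhouette = %s\n", x$K,
              ifelse(is.na(x$silhouette), "NA", sprintf("%.2f", x$silhouette))))
  print(x$means)
  invisible(x)
}

#' @export
tidy.inbox_clusters <- function(x, ...) x$assignments

#' @export
glance.inbox_clusters <- function(x, ...) {
  tibble(K = x$K, silhouette = x$silhouette, loglik = x$loglik,
         n = nrow(x$assignments),
         min_group = min(table(x$assignments$group)),
         max_group = max(table(x$assignments$group)))
}

#' Sweep clustering candidates and select one
#'
#' Fits every combination of candidate component counts, tabulates
#' silhouette and group-size balance, and selects the candidate with the
#' highest silhouette among those whose smallest group has at least
#' `min_group_size` members. If no candidate satisfies the floor the best
#' silhouette is returned with a warning.
#'
#' @inheritParams fit_mixture
#' @param K_values integer vector of candidate component counts
#' @param min_group_size smallest acceptable group (default 5)
#' @return list with `chosen` (an `inbox_clusters`) and `report` (tibble of
#'   all candidates)
#' @export
select_clustering <- function(profiles, K_values = 2:4, seed = 1,
                              min_group_size = 5) {
  fits <- purrr::map(K_values, function(k) fit_mixture(profiles, K = k,
                                                       seed = seed))
  report <- purrr::map2(fits, K_values, function(f, k) {
    sizes <- table(f$assignments$group)
    tibble(K = k, silhouette = f$silhouette, min_group = min(sizes),
           max_group = max(sizes), balance = min(sizes) / max(sizes))
  }) |> list_rbind()
  ok <- report$min_group >= min_group_size & !is.na(report$silhouette)
  pick <- if (any(ok)) {
    which(ok)[which.max(report$silhouette[ok])]
  } else {
    warn("no clustering candidate meets the group-size floor; returning best silhouette")
    which.max(report$silhouette)
  }
  report$chosen <- seq_len(nrow(report)) == pick
  list(chosen = fits[[pick]], report = report)
}

#' Compare profile variables across work-pattern groups
#'
#' Mirrors a groups-by-characteristics comparison table. Each numeric
#' variable is screened for normality (Shapiro-Wilk on within-group
#' residuals) and variance homogeneity (Levene); variables passing both
#' screens are compared by one-way ANOVA with Tukey HSD post hoc, the rest
#' by Kruskal-Wallis with Dunn post hoc. Logical/categorical variables use
#' the chi-square test (Yates continuity correction for 2x2 by default).
#'
#' @param profiles output of [physician_profiles()]
#' @param assignments tibble `physician_id`, `group` (e.g.
#'   `tidy(fit_mixture(...))`)
#' @param vars variables to compare; defaults to every non-id column
#'   present in `profiles`
#' @param alpha screen significance level (default 0.05)
#' @param correct chi-square continuity correction for 2x2 tables
#' @return tibble: `variable`, per-group `mean (SD)` columns, `test`,
#'   `statistic`, `p_value`; post-hoc tables in the `posthoc` list-column
#' @export
compare_groups <- function(profiles, assignments, vars = NULL, alpha = 0.05,
                           correct = TRUE) {
  dat <- profiles |> inner_join(assignments, by = "physician_id")
  if (length(unique(dat$group)) < 2) abort("need at least 2 groups")
  if (is.null(vars)) {
    vars <- setdiff(names(profiles), c("physician_id", "n_days"))
  }
  g <- factor(dat$group)
  rows <- purrr::map(vars, function(v) {
    x <- dat[[v]]
    if (is.numeric(x)) {
      .compare_numeric(x, g, v, alpha)
    } else {
      .compare_categorical(x, g, v, correct)
    }
  })
  list_rbind(rows)
}

.compare_numeric <- function(x, g, v, alpha) {
  ok <- stats::complete.cases(x, g)
  x <- x[ok]; gg <- droplevels(g[ok])
  sizes <- table(gg)
  if (any(sizes < 2) || length(sizes) < 2) {
    return(tibble(variable = v, test = "skipped (group < 2)",
                  statistic = NA_real_, p_value = NA_real_,
                  summary = list(NULL), posthoc = list(NULL)))
  }
  res <- x - stats::ave(x, gg)
  normal <- if (length(res) >= 3 && length(res) <= 5000 && sd(res) > 0) {
    stats::shapiro.test(res)$p.value > alpha
  } else FALSE
  homo <- tryCatch(car::leveneTest(x ~ gg)[1, "Pr(>F)"] > alpha,
                   error = function(e) FALSE)
  grp_summary <- tibble(group = levels(gg),
                        mean = as.numeric(tapply(x, gg, mean)),
                        sd = as.numeric(tapply(x, gg, sd)))
  if (isTRUE(normal) && isTRUE(homo)) {
    fit <- stats::aov(x ~ gg)
    an <- summary(fit)[[1]]
    tibble(variable = v, test = "anova",
           statistic = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
           summary = list(grp_summary),
           posthoc = list(.tidy_tukey(stats::TukeyHSD(fit)$gg)))
  } else {
    kw <- stats::kruskal.test(x, gg)
    tibble(variable = v, test = "kruskal-wallis",
           statistic = unname(kw$statistic), p_value = kw$p.value,
           summary = list(grp_summary),
           posthoc = list(dunn_test(x, gg)))
  }
}

.tidy_tukey <- function(m) {
  tibble(comparison = rownames(m), diff = m[, "diff"],
         p_adj = m[, "p adj"])
}

.compare_categorical <- function(x, g, v, correct) {
  tab <- table(x, g)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  tibble(variable = v, test = "chi-square",
         statistic = unname(ct$statistic), p_value = ct$p.value,
         summary = list(as_tibble(as.data.frame.matrix(tab), rownames = "level")),
         posthoc = list(NULL))
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis omnibus test,
#' with the standard tie correction and Holm-adjusted p values.
#'
#' @param x numeric response
#' @param g grouping factor
#' @param p_adjust_method method passed to [stats::p.adjust()]
#' @return tibble: `comparison`, `z`, `p_value`, `p_adj`
#' @export
dunn_test <- function(x, g, p_adjust_method = "holm") {
  g <- droplevels(factor(g))
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  combs <- utils::combn(levels(g), 2)
  z <- apply(combs, 2, function(pair) {
    i <- pair[1]; j <- pair[2]
    (mr[[i]] - mr[[j]]) /
      sqrt((v0 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  tibble(comparison = paste(combs[1, ], combs[2, ], sep = "-"),
         z = as.numeric(z), p_value = p,
         p_adj = stats::p.adjust(p, method = p_adjust_method))
}
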