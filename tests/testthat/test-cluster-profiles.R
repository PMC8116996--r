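test_that("the mixture recovers tight, well-separated clumps almost perfectly", {
  set.seed(1)
  clump <- function(center, n) {
    tibble::tibble(p_in_hours = pmin(pmax(center[1] + rnorm(n, 0, 0.005), 0.01), 0.98),
                   p_noncontiguous = pmin(pmax(center[2] + rnorm(n, 0, 0.005), 0.01), 0.98))
  }
  prof <- dplyr::bind_rows(clump(c(0.9, 0.02), 12), clump(c(0.3, 0.5), 12))
  prof$p_contiguous <- 1 - prof$p_in_hours - prof$p_noncontiguous
  prof$physician_id <- sprintf("p%02d", seq_len(nrow(prof)))
  fit <- fit_mixture(prof, K = 2, seed = 1)
  expect_gt(fit$silhouette, 0.9)
  expect_equal(dplyr::n_distinct(tidy(fit)$group[1:12]), 1)
  expect_equal(dplyr::n_distinct(tidy(fit)$group[13:24]), 1)
})

test_that("K = 1 yields a single group with undefined silhouette", {
  prof <- draw_prototype_profiles(2)
  fit <- fit_mixture(prof, K = 1, seed = 1)
  expect_true(is.na(fit$silhouette))
  expect_equal(unique(tidy(fit)$group), 1)
})

test_that("a fixed seed reproduces identical assignments", {
  prof <- draw_prototype_profiles(3)
  f1 <- fit_mixture(prof, K = 3, seed = 9, n_restarts = 2)
  f2 <- fit_mixture(prof, K = 3, seed = 9, n_restarts = 2)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("reporting groups are identified by after-hours behaviour", {
  prof <- draw_prototype_profiles(4)
  fit <- fit_mixture(prof, K = 3, seed = 1)
  m <- fit$means
  # group 1 carries the largest noncontiguous share; group 2 is the most
  # work-hours-dominant of the rest
  expect_equal(unname(which.max(m$p_noncontiguous)),
               unname(which(m$group == 1)))
  rest <- m[m$group != 1, ]
  expect_equal(unname(rest$group[which.max(rest$p_in_hours)]), 2)
})

test_that("the candidate sweep prefers K = 3 on three-prototype cohorts", {
  prof <- draw_prototype_profiles(5)
  sel <- select_clustering(prof, K_values = 2:4, seed = 1)
  expect_equal(sel$report$K[sel$report$chosen], 3)
  expect_equal(sel$chosen$K, 3)

  single <- select_clustering(prof, K_values = 3, seed = 1)
  expect_equal(single$chosen$K, 3)
})

test_that("a degenerate single clump triggers the balance warning path", {
  set.seed(10)
  prof <- tibble::tibble(
    physician_id = sprintf("p%02d", 1:20),
    p_in_hours = 0.6 + rnorm(20, 0, 0.01),
    p_noncontiguous = 0.2 + rnorm(20, 0, 0.01))
  prof$p_contiguous <- 1 - prof$p_in_hours - prof$p_noncontiguous
  expect_warning(select_clustering(prof, K_values = 3, seed = 1,
                                   min_group_size = 5),
                 "floor")
})

test_that("group comparisons pick tests by distribution and report posthocs", {
  prof <- draw_prototype_profiles(6)
  assignments <- tibble::tibble(physician_id = prof$physician_id,
                                group = prof$group_true)
  cmp <- compare_groups(prof, assignments,
                        vars = c("p_in_hours", "p_noncontiguous"))
  expect_true(all(cmp$test %in% c("anova", "kruskal-wallis")))
  expect_true(all(cmp$p_value < 0.001))  # prototypes differ strongly
  expect_true(all(vapply(cmp$posthoc, function(p) nrow(p) == 3, logical(1))))
})

test_that("identical groups produce no spurious rejections", {
  set.seed(12)
  prof <- tibble::tibble(physician_id = sprintf("p%02d", 1:45),
                         value = rnorm(45))
  assignments <- tibble::tibble(physician_id = prof$physician_id,
                                group = rep(1:3, each = 15))
  cmp <- compare_groups(prof, assignments, vars = "value")
  expect_gt(cmp$p_value, 0.05)
})

test_that("categorical variables are compared by chi-square", {
  prof <- tibble::tibble(physician_id = sprintf("p%02d", 1:27),
                         batcher = rep(c(TRUE, FALSE), c(6, 21)))
  assignments <- tibble::tibble(
    physician_id = prof$physician_id,
    group = rep(1:2, c(10, 17)))
  # 5/10 vs 1/17 batching contingency
  prof$batcher <- c(rep(TRUE, 5), rep(FALSE, 5), TRUE, rep(FALSE, 16))
  cmp <- compare_groups(prof, assignments, vars = "batcher")
  expect_equal(cmp$test, "chi-square")
  expect_true(is.finite(cmp$statistic))
  expect_lt(cmp$p_value, 0.10)
  tab <- cmp$summary[[1]]
  expect_equal(unname(sort(unlist(tab[, c("1", "2")]))), sort(c(5, 5, 1, 16)))
})

test_that("omnibus tests detect 2-SD group shifts almost always", {
  set.seed(18)
  hits <- vapply(1:50, function(i) {
    prof <- tibble::tibble(
      physician_id = sprintf("p%02d", 1:45),
      value = rnorm(45) + rep(c(0, 2, 4), each = 15))
    assignments <- tibble::tibble(physician_id = prof$physician_id,
                                  group = rep(1:3, each = 15))
    compare_groups(prof, assignments, vars = "value")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the Dunn test matches hand-computed z statistics", {
  x <- c(1, 3, 5, 7, 9, 11, 2, 4, 6)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  d <- dunn_test(x, g)
  # independent hand computation from mean ranks
  r <- rank(x)
  mr <- tapply(r, g, mean)
  v0 <- length(x) * (length(x) + 1) / 12
  z_ab <- (mr[["a"]] - mr[["b"]]) / sqrt(v0 * (2 / 3))
  expect_equal(d$z[d$comparison == "a-b"], unname(z_ab), tolerance = 1e-12)
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
  expect_true(all(d$p_adj >= d$p_value - 1e-12))
})
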