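---
title: "Methods: from access logs and wearable stress scores to an association model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from access logs and wearable stress scores to an association model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inboxstress)
```

`inboxstress` implements a complete analysis chain linking physicians'
EHR inbox work (from audit logs) to physiologic stress (from wearable
HRV stress scores). This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the design
decisions that were genuinely open.

## 1. Time attribution from audit logs

Audit logs record discrete interactions, not durations, and no public
convention fixes how inter-event time becomes "minutes spent". We use
**last-event-carried-forward with an idle cutoff**: each event opens a
half-open interval `[t, min(t_next, t + cutoff))`. The cutoff (default
**5 min**, `idle_cutoff`) caps how much inactivity is credited to the
preceding interaction; the final event of a stream is always credited
exactly the cutoff. This is standard audit-log practice; total attributed
time is monotone in the cutoff, a property the test suite checks against
a per-second brute-force scan.

Minutes are split exactly across hour bins anchored at 30 minutes past
the hour (`bin_anchor = 30`), aligning bins with the 08:30 shift start
(08:30–09:30, 09:30–10:30, …). An interval on a bin boundary belongs to
the later bin. Window switches are adjacent events with different window
identifiers; messages handled are counted from task-completion markers
because the logs deliberately carry no message identifiers or content.

## 2. Temporal classification and batching

Scheduled clinic hours default to 08:30–12:30 and 13:30–17:30,
Monday–Friday (`work_schedule()`); a workday is a weekday with at least
one shift. Daily inbox minutes are partitioned into three components
that always sum to the daily total:

* **work-hours** — inside a shift;
* **contiguous after-hours** — outside shifts, in an activity run whose
  gap to the nearest shift is at most `contiguity_gap` (default
  **60 min**);
* **noncontiguous after-hours** — the rest (late evenings, early
  mornings).

Neither "separate block" nor "contiguous to work hours" has a canonical
operational width, so both are config-exposed. Activity runs and work
blocks merge intervals whose gaps are at most `block_gap` (default
**15 min**): long enough to bridge a quick interruption, short enough
not to fuse a lunch break. A day is **batched** when the largest
`max_blocks = 3` blocks cover at least `coverage_threshold = 0.70` of
its inbox minutes; batching is monotone in `block_gap` (merging can only
concentrate coverage), which is tested as a property. Nonworkday inbox
time is reported separately and excluded from the temporal-split
proportions, which describe workday behaviour.

## 3. Stress-duration measures and validity filters

The wearable reports a 0–100 stress score as 3-minute averages, computed
from HRV only in still moments. A sample is **valid** when a score is
present and no physical activity was registered; each valid sample
contributes its 3 minutes whole — the score is an average over the
window, so sub-sample resolution does not exist. Minutes with score
**> 50** are stress (medium/high); 25–50 is the low band and < 25 rest,
both valid but not stress.

Validity filters guard the ratio estimates: hours need **≥ 20 valid
minutes** (else the stress fraction of a nearly-empty hour is
meaningless) and days need **≥ 2 valid hours**, a scheduled workday, and
some inbox activity. Every stage reports input, removed and percentage
removed, and the filters are idempotent. The daily threshold counts
valid minutes across the whole day, not only work hours — the broader
reading keeps evening-heavy physicians in the daily analyses; it is a
config parameter (`min_day_valid`). Reported percentages are rounded
half-up to whole percent; internal computation is full precision.

## 4. Work-pattern clustering

Each physician's profile is the mean daily temporal split — a point on
the 3-simplex — plus auxiliaries (batched-day fraction, pooled time per
message, message-type shares, nonworkday inbox minutes, demographics).
Because the three proportions sum to one, their covariance is singular;
the Gaussian mixture is fitted on the 2-d **additive-log-ratio (alr)**
coordinates, where a logistic-normal cluster is exactly Gaussian. A
light conjugate prior (`mclust::priorControl()`) regularizes covariances
at n ≈ 47. Components are identified post hoc — component order is
arbitrary — by behaviour: group 1 has the highest mean noncontiguous
after-hours share, group 2 the highest work-hours share of the
remainder. The silhouette is computed on the raw proportions with
Euclidean distance, matching how the feature space is usually shown.
Candidate K values are swept; selection maximizes silhouette subject to
a minimum group size (default 5), falling back with a warning when no
candidate is balanced.

Group comparisons mirror the usual cohort table: Shapiro–Wilk (on
within-group residuals) and Levene screens at α = 0.05 route each
numeric variable to ANOVA + Tukey HSD or Kruskal–Wallis + Dunn;
categorical variables use chi-square with Yates correction for 2×2
(config-exposed — published 2×2 statistics are often not reproducible
from printed counts under either convention, so the correction is not
treated as an exact oracle). The Dunn test is implemented directly (rank
z statistics with tie correction, Holm adjustment) and verified against
hand-computed statistics.

## 5. The Poisson mixed-effects association model

The unit of analysis is the retained physician-day. Work-hours stress
minutes are counts accumulating over the valid measurement window, so
the model is a log-link Poisson GLMM with `log(valid minutes)` as
**exposure offset** (coefficient fixed at 1) and a physician random
intercept:

$$ y_{id} \sim \mathrm{Pois}\big(\lambda_{id}\big),\qquad
\log \lambda_{id} = \log v_{id} + \mathbf{x}_{id}^\top\beta + u_i,\qquad
u_i \sim N(0, \sigma_u^2). $$

Covariates: FTE, age, sex, window-switch rate, work-hours inbox minutes,
work-hours non-inbox EHR minutes, proportion of inbox time outside work
hours, patient-message time share, the batching indicator, and weekday
dummies with Friday as reference. Continuous covariates are
mean-centered (slopes unchanged; intercept interpretable), variance
inflation factors are reported, and zero-variance covariates are dropped
with a warning. Estimation is Laplace-approximate ML via `lme4::glmer`.

Standardized coefficients multiply each slope by the sample SD of its
design column. Marginal and conditional R² use latent-scale variance
partitioning with the log-normal approximation
$\sigma^2_\varepsilon = \ln(1 + 1/\bar\lambda)$ for the observation-level
variance of a Poisson response ($\bar\lambda$ = mean count). With
hundreds of stress minutes per day this observation variance is tiny,
which is why a strong physician intercept yields the characteristic
pattern of a small marginal R² next to a conditional R² near 1.
Overdispersion checks (quasi-Poisson / negative binomial) are possible
via `compare_models()` but off by default — the random intercept absorbs
most extra-Poisson variation at this grain. Model selection across
candidate covariate sets is by AIC.

## 6. What the synthetic cohort emulates

`generate_cohort()` is first-class, tested code: it emits the roster,
log-event and stress streams the readers consume, plus a ground-truth
manifest. Defaults are the study conditions: 47 physicians in groups of
**10 / 17 / 20**, 5 workdays + 2 nonworkdays each, split shifts.

* **Temporal splits.** Per-physician splits are drawn logistic-normally
  on the simplex, with alr parameters **moment-matched by Gauss–Hermite
  quadrature and optimisation** so the realized proportion means and SDs
  equal the configured group prototypes (work-hours share 37/82/62 %,
  etc.). Day-level wobble is added in alr space (`day_alr_sd = 0.25`).
* **Durations.** Daily inbox totals and non-inbox EHR minutes
  (mean 145 min, SD 34, so total EHR ≈ 3.5 h against ≈ 1.08 h inbox) are
  drawn per physician with ~15 % day-to-day coefficient of variation.
* **Exact realization.** An activity run of length L emits events over
  `[start, start + L − cutoff]`, so last-event-carried-forward
  attributes exactly L minutes; runs are separated by ≥ 2 min so the
  cutoff closes each one. Runs shorter than the 5-minute quantum are
  realized probabilistically (one quantum run with probability L/5),
  keeping expectations calibrated. The conservation tests exploit this:
  pipeline minutes equal generated minutes to within timestamp rounding.
* **Batching.** Physicians are batchers with group-specific probability
  (0.50 / 0.06 / 0.30 — the third value is a design choice placed
  between the other two, which are pinned by the prototype definitions);
  batcher days concentrate inbox work in ≤ 3 long runs, non-batcher
  days spread it over ≥ 4 runs.
* **Messages and switching.** Handled messages are emitted as
  zero-duration marker events at sampled inbox timestamps (a zero-gap
  event attributes no time), so per-message handling time
  (0.46 / 0.35 / 0.38 min) is recovered without distorting minutes.
  Window identifiers switch with a per-day probability scaled to hit
  ≈ 4.25 switches per EHR minute.
* **Stress.** Scores follow baseline + three Gaussian bumps over clock
  time (centers 9:00, 13:45, 20:00) + physician intercept
  (`sigma_u = 10` score points) + noise (`sigma_e = 12`), clamped to
  [0, 100] and rounded. Group baselines and the common amplitude are
  **calibrated by probit inversion** (threshold 50.5 to respect integer
  rounding) so expected work-hours stress fractions hit the group
  targets (33/18/22 %) and the cohort first-work-hour mean hits 35 %.
  Dropout is generated as contiguous device-off episodes (overnight
  charging, daytime gaps, activity periods), not i.i.d. minutes, so the
  20-min/2-h filters are exercised realistically; defaults leave roughly
  240–260 valid work-hours minutes per day.

**What it does not emulate:** real within-physician day-to-day
correlation of usage (physician-level random effects only), any causal
day-level coupling between usage covariates and stress (the default
cohort carries group-level stress differences only; effectful
physician-day frames for model validation come from
`simulate_stress_days()`, which injects known coefficients), weekend
clinical work, vendor-specific log semantics, and the device's internal
HRV-to-score algorithm. Passing recovery tests therefore demonstrates
that the pipeline measures what the generator encodes — not that real
cohorts will show the same effect sizes.

## 7. Numerical choices and degenerate inputs

* Timestamps are wall-clock POSIXct (UTC) at second resolution; minutes
  are continuous doubles; conservation tolerances are 1e-6 min in exact
  stages and 0.5 min/day end-to-end (second rounding).
* Empty event streams, zero-inbox days, zero valid minutes, zero
  messages and zero EHR minutes all return empty results or `NA` rather
  than errors; unsorted or schema-violating events are rejected loudly.
* Mixture fits: singular covariances are handled by the conjugate prior;
  `fit_mixture` retries up to `n_restarts` and keeps the best
  log-likelihood; a fixed seed makes assignments reproducible.
* `glmer` runs with default Laplace settings; non-convergence is
  reported via `converged` and excluded from model comparison, never
  silently replaced.

## 8. Known limitations

* With the configured between-physician dispersions, groups 1 and 3
  overlap substantially in the temporal-split feature space; even the
  Bayes-optimal classifier misassigns a few physicians per cohort at
  n = 47, and a fitted mixture misassigns more. The work-hours-dominant
  group is essentially always recovered cleanly; the two after-hours
  groups are not fully separable. Cohort-level conclusions should not
  hinge on individual group-1-vs-3 assignments.
* Per-message time divides pooled inbox minutes by completed tasks;
  physicians with very little inbox time have noisy ratios, so profiles
  use the pooled (not day-averaged) estimator.
* The stress model treats days as exchangeable given the physician
  intercept; serial correlation across consecutive days is not modelled.

## 9. Problem sizes used in the checks

The test suite runs the full pipeline on the default 47-physician,
7-day cohort once (a few hundred thousand log events, ~30 s), smaller
12-physician cohorts for pipeline mechanics, 200 replicate null fits of
the GLMM at 40 physicians × 5 days for the type-I-error check, and
12 replicate prototype cohorts for cluster recovery. These sizes give
Monte-Carlo error well inside the 2-standard-error acceptance bands
while keeping a complete run in a few minutes.
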