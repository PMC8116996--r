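# inboxstress

Physicians do a large share of their electronic health record (EHR) work
inside the **inbox** (patient messages, results, requests, administrative
notices), and that work spills past clinic hours. `inboxstress` is an R
package for studying how inbox work patterns relate to **physiologic
stress** measured by wrist-worn heart-rate-variability (HRV) sensors. It
is aimed at occupational digital-health and clinical-informatics
researchers who have (or want to simulate) two streams of data per
physician: timestamped EHR access-log events and 3-minute wearable stress
scores on a 0–100 scale.

## What it computes

1. **Sessionization and hourly features.** Raw audit-log events become
   attributed time via last-event-carried-forward with an idle cutoff
   (default 5 min). Minutes are binned into schedule-aligned hours
   (08:30–09:30, …) by activity (inbox vs other EHR work) and message
   type, together with window switches and completed tasks.
2. **Temporal patterns.** Each day's inbox minutes are partitioned into
   work-hours, *contiguous* after-hours (activity runs adjoining a shift
   boundary) and *noncontiguous* after-hours (e.g. late evening). Inbox
   work **batching** flags days where the top 3 work blocks cover ≥ 70 %
   of the day's inbox time.
3. **Stress quantification.** Each valid 3-minute sample (score present,
   no physical activity) contributes valid minutes; scores > 50
   contribute stress minutes. Hours with < 20 valid minutes and days with
   < 2 valid hours are removed, with a full removal report. The daily
   stress curve shows the three-wave pattern (first work hour, early
   afternoon, evening).
4. **Work-pattern clustering.** Physician profiles (mean daily temporal
   split) are clustered with a Gaussian mixture model on the
   additive-log-ratio representation of the 3-proportion simplex; groups
   are compared by ANOVA/Tukey or Kruskal–Wallis/Dunn and chi-square.
5. **Stress association model.** Work-hours stress minutes per
   physician-day are modelled as
   `stress ~ Poisson(exp(Xβ + u_i) · valid_minutes)` — a log-link Poisson
   GLMM with `log(valid minutes)` as exposure offset and a physician
   random intercept `u_i`; reported with standardized coefficients and
   latent-scale marginal / conditional R².
6. **Synthetic cohorts.** `generate_cohort()` emits rosters, log-event
   streams and stress series from three behavioural group prototypes
   (moment-matched logistic-normal temporal splits, calibrated 3-wave
   stress model, contiguous sensor-dropout episodes), with a ground-truth
   manifest so every stage is testable without any external data.

## Worked example

```r
library(inboxstress)
library(dplyr)

cohort <- generate_cohort(cohort_config(seed = 1))
pipe   <- run_pipeline(cohort)

pipe$descriptives
#> # A tibble: 8 × 4
#>   statistic                           unit       mean     sd
#>   <chr>                               <chr>     <dbl>  <dbl>
#> 1 workday EHR time                    hours/day  3.52  0.684
#> 2 workday inbox time                  hours/day  1.04  0.341
#> 3 nonworkday EHR time                 min/day   28.5  23.3
#> 4 nonworkday inbox time               min/day   15.4  22.4
#> 5 patient-message share of inbox time %         37.8   8.68
#> ...
```

Physicians in this simulated cohort spend ~3.5 h/day in the EHR, about
1 h of it in the inbox, with patient messages the largest share — the
conditions the generator is configured to. Clustering recovers the three
temporal patterns:

```r
pipe$clusters
#> <inbox_clusters> K = 3, silhouette = 0.21
#> group 2 (n = 13) is work-hours-dominant: mean work-hours share 0.821

glance(pipe$model)
#> conditional R² = 0.991 ≫ marginal R² = 0.029: stable individual
#> differences dominate day-level stress variation
```

`stress_fraction(80, 243)` returns `33` — 33 % of a 243-minute valid
measurement window spent at medium/high stress.

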