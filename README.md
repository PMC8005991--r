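# opposcreen

Screening carpal tunnel syndrome (CTS) from smartphone thumb-reaching
trajectories.

CTS compresses the median nerve at the wrist and impairs thumb opposition.
A reaching game — slide the thumb from the screen center to targets in 12
directions on a 2-cm circle, 5 seconds per reach — exposes this
impairment without clinical equipment. `opposcreen` implements the full
analysis pipeline for such recordings, for researchers evaluating
movement-based screens and for anyone building similar one-class screening
pipelines:

1. **Kinematics** — per-direction time to collect, mean and maximum thumb
   velocity, with Student t / chi-square group comparisons.
2. **Encoding** — each hand's second lap becomes a 12 × 50 grayscale
   image: rows are directions, columns the 10-Hz frame grid, and pixel
   intensity is the normalized distance to the center
   `min(‖(x, y)‖ / r, 1)`. The collection frame is set to 1.0 and every
   later frame to 0.0. Flattened row-major, a hand is a 600-vector
   (4-direction windows give 200-vectors).
3. **Anomaly detection** — a 600–10–600 autoencoder trained on healthy
   hands only; the screening score of a hand is the mean squared
   reconstruction error `MSE = mean((x − x̂)²)`, small for healthy-looking
   movement and large for anomalous movement.
4. **Evaluation** — ROC curve over all score cutoffs (positive class =
   CTS, trapezoidal AUC ≡ Mann–Whitney probability), Youden-optimal
   cutoff `max(sens + spec − 1)`, confusion matrix, and a 12-window sweep
   that retrains the detector on every set of 4 consecutive directions to
   localise the signal.
5. **Simulation** — a minimum-jerk reaching simulator generates seeded
   case-control cohorts (global slowing plus an opposition-direction
   penalty for impaired hands), so every stage is testable without
   clinical data.

## Worked example

```r
library(opposcreen)

# a seeded synthetic cohort at a typical clinical-study scale:
# 27 healthy hands, 36 CTS hands, two laps of 12 directions each
sessions <- simulate_cohort(n_healthy = 27, n_cts = 36, seed = 7)

# per-direction group comparison (second lap)
kin <- cohort_kinematics(sessions, lap = 2)
head(compare_groups(kin), 3)
#> # A tibble: 3 × 8
#>   direction metric          group_a group_b mean_a mean_b t_statistic  p_value
#>       <int> <chr>           <chr>   <chr>    <dbl>  <dbl>       <dbl>    <dbl>
#> 1         1 time_to_collect healthy cts      0.727   1.25       -2.93 4.73e- 3
#> 2         1 mean_velocity   healthy cts      3.08    2.23       11.4  7.93e-17
#> 3         1 max_velocity    healthy cts      6.90    4.98       11.0  4.69e-16

# train on 12 healthy hands, score the other 51, evaluate
res <- run_screening(sessions, n_train = 12, seed = 1, sweep = TRUE)
res
#> <cts_screening> 51 validation hands (12 trained): AUC 0.961,
#>   sensitivity 100%, specificity 93% at Youden cutoff 0.05921
res$sweep[res$sweep$window == "8-11", ]
#> # A tibble: 1 × 5
#>   window start sensitivity_pct specificity_pct   auc
#>   <chr>  <int>           <dbl>           <dbl> <dbl>
#> 1 8-11       8             100             100     1
```

Reading: the impaired group is slower in every direction (here direction
1: 1.25 s vs 0.73 s to collect, mean velocity 2.23 vs 3.08 cm/s). The
full-image model separates the 36 CTS from the 15 held-out healthy hands
with AUC 0.96; at the Youden-optimal MSE cutoff it calls every CTS hand
(sensitivity 100%) at 93% specificity. The window sub-model built from
the opposition-like directions 8–11 separates the groups perfectly on this
cohort, as expected when the impairment loads on those directions.

Real recordings in the flat session CSV format (one row per sample:
`hand_id, group, side, severity, lap, direction, collected, t, x, y`) go
through `read_sessions()` and the same calls. A thin command-line front
end for the whole pipeline ships in `inst/cli/opposcreen.R`
(`simulate`, `kinematics`, `encode`, `train`, `score`, `evaluate`,
`sweep`, `run`).

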