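# nbdcdep

Digital phenotyping of depressive symptom severity from the **nearby
Bluetooth device count** (NBDC): the hourly number of Bluetooth devices a
participant's phone detects. The NBDC is a mixed proxy for social
interaction, working status, mobility and isolation, and its structure
shifts with depressive state — as symptoms worsen, the amount of the signal
falls, its variance falls, its circadian rhythm weakens and the sequence
becomes more irregular. `nbdcdep` turns that observation into a tested,
reproducible pipeline for researchers working with passive mobile-sensing
streams and biweekly PHQ-8 questionnaires.

The package provides:

* **Synthetic cohorts** (`generate_cohort()`): hourly Poisson NBDC series
  with participant baselines, a 24-hour circadian sinusoid, weekday
  effects, configurable missingness, and latent-severity coupling on four
  channels (amount, variance, circadian amplitude, irregularity), paired
  with clipped-AR(1) PHQ-8 trajectories and baseline demographics.
* **Preprocessing** (`build_intervals()`): 14-day look-back windows per
  questionnaire, valid days (≥ 12 observed hours), valid intervals
  (≥ 10 valid days), linear interpolation of missing hours, and a
  rejection log naming the failed criterion per dropped record.
* **49 Bluetooth features** (`extract_features()`): 16 second-order
  statistics of daily summaries (`Mean_Max`, `Std_Std`, …), multiscale
  sample entropy `MSE_1`–`MSE_24` (m = 2, r = 0.2 × SD), and periodogram
  band powers, fractions and spectral entropies in the LF (0–0.75],
  MF (0.75–1.25] and HF (1.25–12] cycles/day bands.
* **Association screening** (`associate_features()`): per-feature linear
  mixed-effects models with random participant intercepts and demographic
  covariates, z-tests, Benjamini–Hochberg correction; plus the nested
  likelihood-ratio ladder A (demographics) ⊂ B (+ 16 second-order
  features) ⊂ C (+ all 49 features).
* **Hierarchical Bayesian prediction** (`fit_hierarchical()`, `run_cv()`):
  partially pooled participant intercepts and last-observed-score slopes,
  shrinkage priors on the 49 feature slopes, Gibbs sampling with
  interweaved scale updates, evaluated under leave-all-out (rolling
  origin, T−1 folds) and leave-one-out (J folds) time-series
  cross-validation with an automated temporal-leakage audit; pooled
  predicted R² and RMSE.

## Worked example

```r
library(nbdcdep)

cfg    <- cohort_config(n_participants = 30, followup_days = 84, seed = 42)
cohort <- generate_cohort(cfg)
iv     <- build_intervals(cohort$scans, cohort$phq8, cohort$demographics)
iv
#> <nbdc_intervals> 180 retained interval(s), 0 rejection(s)

ft    <- extract_feature_table(iv, cohort$demographics)   # 180 x 58
assoc <- associate_features(ft)
sig   <- assoc[!assoc$flagged & assoc$p_adjusted < 0.05, ]
head(sig[order(sig$p_adjusted),
         c("feature_name", "estimate", "se", "z", "p_adjusted")])
#>    feature_name estimate     se     z p_adjusted
#> 15    Mean_Mean   -3.400 0.1571 -21.6  3.14e-102
#> 11     Mean_Std   -3.711 0.1964 -18.9   3.06e-78
#> 45       MF_pct  -26.683 1.4720 -18.1   3.20e-72
#> 3      Mean_Max   -0.951 0.0544 -17.5   2.47e-67
#> 13     Max_Mean   -2.315 0.1378 -16.8   2.59e-62
#> 46       HF_pct   27.696 1.7097  16.2   4.16e-58
```

Estimates are in PHQ-8 points per unit of the raw feature: higher mean
NBDC level (`Mean_Mean`), daily variance (`Mean_Std`) and circadian power
fraction (`MF_pct`) all go with *lower* severity, while a larger
high-frequency share (`HF_pct`) — a noisier, less rhythmic day — goes with
higher severity. These are the coupling directions the generator encodes,
recovered from the counts.

```r
sp   <- hier_spec(draws = 300, warmup = 300, chains = 2, seed = 42)
full <- run_cv(ft, "lao", "full", sp)
base <- run_cv(ft, "lao", "baseline", sp)
c(full = full$metrics$r2, baseline = base$metrics$r2)
#> LAO full:     R2 = 0.588, RMSE = 2.561, n_test = 110
#> LAO baseline: R2 = 0.413, RMSE = 3.059, n_test = 110
```

The Bluetooth features lift pooled leave-all-out R² well above the
baseline that only knows the last observed score and demographics — the
package's headline comparison.

The whole chain (simulate → preprocess → features → associate → predict)
also runs as one call from a YAML configuration, writing every stage's
CSVs plus a manifest with seed, settings and input checksums:

```r
run_pipeline(system.file("extdata", "example_config.yaml", package = "nbdcdep"))
```

or from a shell via the thin wrapper
`Rscript inst/cli/nbdc.R run --config config.yaml --out DIR`.

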