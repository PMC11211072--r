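# neurodim

Neuroanatomical dimensions of major depressive disorder (MDD) from
regional brain volumes, by semi-supervised max-margin clustering.

Case–control studies of depression average over a biologically
heterogeneous patient group. `neurodim` implements the dimensional
alternative for researchers working with multi-site structural-MRI
cohorts: given a table of per-subject ROI volumes (patients and healthy
controls), it

- **harmonizes** site batch effects with an empirical-Bayes
  location/scale model while protecting the diagnosis signal, removing
  site, age and sex effects;
- **clusters** patients into *k* dimensions HYDRA-style: each dimension
  *j* owns a linear max-margin hyperplane (w_j, b_j) separating *its*
  patients from the whole control group (a "1-to-k" mapping), fit by
  alternating SVM training and reassignment to the dimension with the
  largest normalized score (w_j·x + b_j)/‖w_j‖;
- **selects k** (2–5) by stability: the mean pairwise Adjusted Rand
  Index (ARI) of assignments across seeded patient subsamples, with
  consensus (majority-vote) final labels;
- **validates** by split-sample replication and leave-site-out
  cross-validation with percentage-overlap of aligned assignments;
- **maps** each dimension against controls at ROI level: covariate-
  adjusted Welch comparisons, signed Cohen's d, Benjamini–Hochberg
  masking at q < 0.05;
- **models treatment response**: percentage change in HAM-D,
  (pre − post)/pre × 100, regressed on dimension × treatment (binary
  SSRI/placebo or four-arm), Cohen's f² and noncentral-F power for the
  interaction, and a continuous variant using the signed hyperplane
  distance between the two dimensions.

A synthetic multi-site cohort generator (`generate_cohort()`,
`generate_outcomes()`) reproduces the statistical structure this
analysis assumes — a "preserved" subtype, a subtly reduced subtype, site
batch effects, covariate effects, and subtype-dependent trial outcomes —
so the entire pipeline runs and is tested without any imaging data.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

A cohort at the generator's defaults — 200 controls, two patient
subtypes of 200 (one preserved, one reduced by d = 0.4 in 40% of 259
ROIs), 3 sites:

```r
library(neurodim)
library(dplyr)

cohort     <- generate_cohort(cohort_spec(seed = 42))
harmonized <- apply_harmonization(cohort, fit_harmonization(cohort))

report <- select_k(harmonized, k_range = 2:4, n_subsamples = 5,
                   restarts = 1, seed = 42)
tidy(report)
#>       k stability_ari n_pairs
#>   <int>         <dbl>   <int>
#> 1     2         0.837      10
#> 2     3         0.577      10
#> 3     4         0.334      10

model <- consensus_assign(report)
count(tidy(model), dimension)
#>   dimension     n
#> 1         1   212
#> 2         2   188
```

k = 2 is clearly the most stable solution and the consensus split is
212/188. Mapping each dimension against controls identifies which one
carries the anatomy (dimension labels are arbitrary until you look at
the maps):

```r
labelled <- harmonized |>
  left_join(tidy(model), by = "subject_id") |>
  mutate(contrast_group = if_else(group == "control", "control",
                                  paste0("D", dimension)))
map_d2 <- group_difference_map(labelled, contrast = c("D2", "control"),
                               group_col = "contrast_group")
#> D1 vs controls: 0/259 ROIs significant
#> D2 vs controls: 100/259 ROIs significant, mean signed d = -0.42
```

Dimension 1 is anatomically preserved; dimension 2 shows widespread
subtle volume reductions. The planted treatment structure (D1 responds
to SSRI but not placebo; D2 responds to both) surfaces as a negative
dimension-by-treatment interaction on percentage HAM-D change:

```r
outcomes <- generate_outcomes(cohort, trial_spec(seed = 43)) |>
  inner_join(tidy(model), by = "subject_id")
fit_interaction(outcomes, arms = "binary") |>
  tidy() |> filter(interaction)
#>   term              estimate conf_low conf_high  p_value
#> 1 .dimD2:.treatssri    -20.3    -30.8     -9.71 0.000185
```

i.e. the SSRI-over-placebo advantage is 20.3 percentage points smaller
in D2 than in D1. The analytic power of this interaction test at
f² = 0.06, n = 359 with six additional covariates:

```r
power_partial_f(0.06, 359, n_extra_covariates = 6)
#> [1] 0.9956
```

`run_pipeline(demo_config())` chains all stages end-to-end and writes
CSV/JSON artifacts plus a seed-stamped manifest.

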