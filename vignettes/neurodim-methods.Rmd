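---
title: "Methods: neuroanatomical dimensions of depression from ROI volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuroanatomical dimensions of depression from ROI volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodim)
```

## The problem

Major depressive disorder (MDD) is clinically and biologically
heterogeneous; case–control comparisons of brain structure average over
that heterogeneity and tend to produce weak, diffuse effects. `neurodim`
implements a dimensional alternative: instead of asking "how do patients
differ from controls on average?", it asks "how many distinct ways do
patients differ from controls, and which patient expresses which?". The
substrate is a subjects-by-regions table of gray/white-matter volumes
(mm³) for a set of anatomical regions of interest (ROIs, 259 by default,
matching a modern multi-atlas segmentation), with per-subject covariates
(site, age, sex, episode history) and, for a treated subset, pre/post
depression ratings on the 17-item Hamilton scale (HAM-D).

## The clustering model

The core is a HYDRA-style semi-supervised max-margin clustering. Patients
are partitioned into $k$ *dimensions*; each dimension $j$ owns a linear
hyperplane $(w_j, b_j)$ trained to separate *that dimension's patients*
(label $+1$) from the *whole healthy-control group* (label $-1$) — a
"1-to-k" mapping. Clustering is therefore driven by how patients deviate
from controls, not by how patients resemble one another; a patient
subgroup that does not deviate from controls at all is still a valid
dimension (its hyperplane simply carries little margin).

Fitting alternates:

1. given assignments, fit one soft-margin linear SVM per dimension
   (hinge loss, penalty below);
2. given hyperplanes, reassign every patient to the dimension with the
   largest normalized signed score $(w_j \cdot x + b_j)/\lVert w_j \rVert$,
   ties to the lowest index;

until assignments are unchanged (or `max_iter = 50` sweeps). Features are
z-scored per ROI against *control* statistics first, so hyperplane
coefficients are comparable across regions and a control-shaped patient
sits at the origin.

**Penalty parameterization.** `cost` is a *total* hinge budget spread over
the expected subproblem size: the per-observation penalty is
$C = \mathrm{cost}/(n_c + n_p/k)$, with the patient class up-weighted by
$n_c/(n_p/k)$ to balance the larger control group. Two properties
motivated this: (i) the regularization strength is invariant to cohort
size, and (ii) per-observation penalties of order 1 let a
"preserved-volumes" patient subgroup be spuriously separated from controls
in a few hundred dimensions, which destabilizes the alternation — on
planted-structure cohorts the recovery of the true assignment is flat over
`cost` roughly 2–8 and collapses outside it, so the default is
`cost = 4`. Both penalty weights are frozen across iterations, which makes
the recorded objective
$\sum_j \tfrac12\lVert w_j\rVert^2 + \sum_i C_i\,\mathrm{hinge}_i$
the exact quantity the alternation decreases; its trace is stored on every
model, and a property test asserts it never deteriorates beyond solver
tolerance ($10^{-3}$ relative).

**Initialization.** The first restart seeds assignments with k-means
(Hartigan–Wong, 3 starts) on the standardized patient features; the
remaining `n_restarts - 1` restarts use random assignments with every
dimension inhabited. The restart with the lowest final objective wins. All
randomness is seeded.

**Empty dimensions.** If a reassignment sweep empties a dimension, it is
reseeded with the patient farthest below all current hyperplanes (most
negative best score) — the patient least well explained by the current
model.

## Choosing the number of dimensions

`select_k()` scans $k = 2..5$ (the range a small number of clinically
distinct dimensions is expected to occupy). For each $k$ it refits on
seeded 90% subsamples of the patients (controls always fully included) and
scores *stability*: the mean pairwise Adjusted Rand Index (ARI) of the
assignments over the patients two subsamples share. The chosen $k$
maximizes mean stability, ties to the smallest $k$. The ARI is the Rand
index — the fraction of subject pairs on which two partitions agree —
rescaled under the fixed-margin permutation null so that identical
partitions score 1 and independent ones score 0 in expectation; both the
pair-counting and contingency-table routes are implemented and proven
equal on enumerated partitions in the test suite.

If no $k$ reaches `reliable_min = 0.3`, the report carries a
`no_reliable_dimensions` flag: on cohorts with no planted structure the
stability scan stays near zero for every $k$ (the default scan uses
subsample fits seeded by k-means, so this is a genuine property of the
data, not of the restarts). The default of 20 subsamples (reduced in the
examples and tests, where 4–5 subsamples already give 6–10 ARI pairs) and
`restarts = 2` for the scan reflect that the scan averages over many fits
and does not need each fit to be globally optimal.

Final labels come from `consensus_assign()`: subsample assignments are
aligned by maximum-overlap (Hungarian-style, exact over the $k! \le 120$
permutations) matching, majority-voted per patient, the patient-by-patient
co-assignment matrix is emitted, and a last fit initialized from the
consensus labels yields the reported hyperplanes.

For $k = 2$, `hyperplane_distance()` trains a separating classifier
*between* the two dimensions and returns each patient's signed,
norm-scaled distance (positive = dimension-2 side) — a continuous
assignment-certainty score that can replace the hard label in outcome
models.

## Site harmonization

Multi-site volumes carry scanner/site batch effects. `fit_harmonization()`
implements the empirical-Bayes location/scale model that is standard for
multi-site imaging features: per-ROI covariate regression (linear age,
additive sex) with site indicators, standardization on pooled residual
scale, per-site/per-ROI shifts $\gamma$ and scales $\delta^2$, shrunk
toward moment-matched normal and inverse-Gamma priors by the usual
iterative posterior solution (`eb = FALSE` gives the unshrunk
location/scale variant for testing). Diagnosis is a *protected* covariate
in the design, so case–control differences are not absorbed into site
terms, and its effect is restored on output.

One consequential choice: the adjustment target is "site, age and sex",
so `apply_harmonization()` *removes* the nuisance covariate effects along
with the batch effects by default. The conventional ComBat behavior
(remove site only, restore age/sex) is available via
`restore_covariates = TRUE`, and in that mode the output matches the
reference implementation in `sva::ComBat` to correlation > 0.9999 (a
suite cross-check). The default matters in practice: age induces a strong
shared axis across all ROIs, and clustering un-ageing-corrected features
recovers age strata instead of anatomy — on planted-structure synthetic
cohorts the truth ARI moves from ≈ 0 to ≈ 0.8 when age/sex are removed.

The fitted model is a frozen object: it can be applied to held-out
subjects from the training sites (unseen sites are an error — no
extrapolation) and serializes to JSON.

## Effect maps

`group_difference_map()` is the ROI-resolution analog of a voxel-wise
statistical parametric map: covariates are removed per ROI by linear
regression, each ROI gets a Welch two-sample comparison between the
contrast groups, effects are signed Cohen's d (positive = larger in
patients), and p-values are Benjamini–Hochberg adjusted within the map,
masked at $q < 0.05$. Subgroup contrasts (one dimension versus controls,
first-episode only, extra covariates such as years of education or the
episode-history proxy for medication exposure) are expressed by filtering
or relabeling the table first — ordinary dplyr operations, no special
API. Under the global null the false-flag proportion is at the nominal
level (checked over 200 simulated cohorts).

## Outcome statistics

The trial outcome is percentage change,
$(\mathrm{pre} - \mathrm{post})/\mathrm{pre} \times 100$, positive =
improvement. `fit_interaction()` fits OLS with dimension (reference D1)
by treatment (reference placebo) interaction, controlling for age, sex
and site; `arms = "four_arm"` keeps sertraline / escitalopram /
citalopram / placebo separate with one interaction per drug. On a
noiseless balanced design the interaction estimate equals the
difference-in-differences of the cell means to $10^{-10}$ (a suite
property), e.g. $(46.9 - 42.2) - (51.1 - 28.6) = -17.8$ percentage points
for the default generator cells. Significance is two-sided at 0.05 with
no multiplicity correction across the drug-specific interactions,
matching common trial-report practice for secondary contrasts.

Effect size and power: Cohen's
$f^2 = (R^2_{full} - R^2_{reduced})/(1 - R^2_{full})$, and
`power_partial_f()` evaluates the noncentral-F power of the partial-F
test. Denominator df are
$n - \mathrm{df}_{num} - n_{\mathrm{main}} - n_{\mathrm{extra}} - 1$
(main terms default 2, the dimension and treatment columns implied by a
binary interaction; site enters real models as several dummies, so the
count of extra covariates is supplied directly). The noncentrality
convention is $\lambda = f^2(\mathrm{df}_{num} + \mathrm{df}_{den} + 1)$,
the common power-software choice; $\lambda = f^2 n$ is available behind
`lambda = "n"`, and both give > 99% power at $f^2 = 0.06$, $n = 359$ with
six extra covariates (and at $f^2 = 0.13$ with ten), so nothing rests on
the convention.

`cohort_table_tests()` covers the demographic table: chi-square test of
independence for sex (uncorrected by default; Yates via `correct = TRUE` —
at cohort-scale counts the two round to the same 2-decimal p) and
two-sided Mann–Whitney U for continuous variables.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the analysis assumes,
so every downstream stage is testable without imaging data:

- a per-cohort ROI mean template drawn log-normal around plausible
  volumes (median 8 cm³, log-sd 0.5), within-group noise Gaussian with a
  12% coefficient of variation — positivity plus simple effect-size
  arithmetic;
- two (or more) patient subtypes: subtype 1 *preserved* (drawn from the
  control distribution), subtype 2 reduced by `effect_size_d` control
  s.d. in a seeded random `affected_fraction` (default 40%) of ROIs; a
  vector `effect_size_d` gives every subtype its own depth on disjoint
  ROI sets (used for well-separated test fixtures);
- disease effects applied *before* site and covariate effects,
  additively on the ROI scale — matching the harmonize-then-cluster
  pipeline assumptions;
- site batch effects: additive per-site/per-ROI shifts (s.d. 150 mm³)
  and multiplicative log-normal factors (s.d. ≈ 0.1) on the residual
  noise — the generative model the harmonizer assumes;
- linear age effect (−15 mm³/yr around the adult midpoint 41.5 yr), an
  additive male–female offset (400 mm³), age uniform 18–65, ~60% female,
  episode type Bernoulli (27% first-episode) independent of subtype;
- all ground truth (affected ROI identities, planted site parameters,
  template moments) emitted as metadata for scoring.

`generate_outcomes()` allocates patients to
sertraline/escitalopram/citalopram/placebo with probabilities matching a
359-patient prospective sample (98/116/36/109), draws HAM-D baselines
from a normal with mean 20.5 and s.d. 4.1 truncated below at the
inclusion floor of 14 (rejection sampling; the realized mean sits
slightly above 20.5, which is faithful to how an inclusion criterion
acts), and applies a per-(subtype, arm) mean percentage reduction — by
default D1: 51.1% on any SSRI vs 28.6% on placebo; D2: 46.9% vs 42.2% —
plus individual noise (s.d. 25 percentage points, a realistic spread for
percentage change in trials), with
$\mathrm{post} = \mathrm{round}(\mathrm{pre}(1 - pct/100))$ clipped at 0.

What the generator does **not** emulate: intracranial-volume confounding
(the upstream analysis is ambiguous about ICV normalization, so no ICV
axis is planted), non-linear age effects, site-by-diagnosis confounding,
missing data, dropout, scanner software upgrades mid-study, or any
voxel-level structure. Passing tests therefore demonstrate correctness of
the machinery under the stated statistical model, not robustness to every
failure mode of real multi-site MRI.

## Stability protocols

`split_sample()` halves the cohort stratified jointly by group, site, sex
and age tertile (site-only fallback with a warning when joint strata are
too sparse), runs the full selection+consensus pipeline per half, and
reports whether the halves agree on $k$ plus the sign agreement of their
dimension-versus-control effect maps after best-correlation alignment.
`leave_site_out()` drops one site at a time, refits (fixed at the
reference $k$ by default; `reselect_k = TRUE` re-runs the scan and flags
folds that choose a different $k$), aligns labels to the full-sample
reference, and reports per-site percentage overlap with min/mean/max.
Overlap is computed only over patients present in both analyses and is
invariant to relabeling by construction.

## Numerical choices and degenerate cases

- ARI of two single-cluster partitions is defined as 1 with a message
  (agreement is perfect; the chance adjustment is 0/0).
- Constant ROIs are exempted from harmonization with a warning.
- Zero-variance Welch denominators fall back to $t = 0, p = 1$.
- Label alignment is exact enumeration over $k!$ permutations
  ($k \le 5$).
- Every seeded stage derives child seeds through `child_seed()` (a fixed
  affine map kept below $2^{31}$), so a stage run standalone reproduces
  its in-pipeline output.

## Problem sizes

The test suite and examples run planted-structure cohorts of 200–600
subjects with 24–259 ROIs; the dimension-recovery property (k = 2 chosen
in ≥ 9/10 replicates at planted d = 0.4, 40% of 259 ROIs affected,
200/200/200 subjects, 3 sites) uses 5 subsamples per candidate k. These
sizes were chosen as the smallest at which the subtle-reduction regime is
genuinely detectable: at 50 ROIs the same planted d = 0.4 is *below* the
practical detection threshold of the method (total between-subtype
separation grows like $d\sqrt{0.4\,p}$ against a noise dimension of $p$),
which is itself an instructive property of dimensional analyses at this
effect size.

## Known limitations

- The hard-assignment HYDRA variant is implemented (each patient in
  exactly one dimension); no soft memberships beyond the consensus
  matrix, no nonlinear kernels.
- Harmonization assumes location/scale batch effects and linear
  covariates; no GAM age curves.
- The stability scan's subsample fits share 80%+ of their subjects, so
  stability is evidence of *internal* reproducibility, not external
  replication — that is what `split_sample()` and `leave_site_out()`
  probe.
- Outcome models are OLS on percentage change; no mixed effects,
  repeated measures, imputation, or causal analysis.
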