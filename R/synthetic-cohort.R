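#' Specify a synthetic multi-site case-control cohort
#'
#' Describes a cohort of healthy controls and patients carrying planted
#' neuroanatomical subtypes. Subtype 1 is "preserved" (drawn from the
#' control distribution); by default every further subtype shows a
#' standardized reduction of `effect_size_d` control within-group standard
#' deviations in a random `affected_fraction` of ROIs. Site batch effects
#' (additive per-site/per-ROI shifts, multiplicative scale factors on the
#' residual noise) and linear age and sex effects are layered on after the
#' disease effect, mirroring the harmonize-then-cluster assumptions of the
#' analysis pipeline.
#'
#' @param n_controls Number of healthy controls.
#' @param n_patients_per_subtype Integer vector; one count per true subtype.
#' @param n_rois Number of regions of interest (volumes in mm^3).
#' @param affected_fraction Proportion of ROIs reduced in affected subtypes.
#' @param effect_size_d Cohen's d of the planted reduction in affected ROIs.
#'   A scalar applies to subtypes 2..K (subtype 1 stays preserved); a vector
#'   of length K gives each subtype its own d, and subtypes with d > 0
#'   receive disjoint affected ROI sets.
#' @param n_sites Number of acquisition sites.
#' @param site_shift_sd S.d. of additive per-site/per-ROI shifts (mm^3).
#' @param site_scale_sd S.d. of multiplicative site factors around 1
#'   (applied to the residual noise, log-normal so factors stay positive).
#' @param age_slope Volume change per year of age (mm^3/yr, negative).
#' @param sex_offset Male minus female volume offset (mm^3).
#' @param prop_first_episode Probability a patient is first-episode (vs
#'   recurrent), independent of subtype.
#' @param prop_female Probability a subject is female.
#' @param roi_mean_meanlog,roi_mean_sdlog Log-normal hyperparameters of the
#'   per-cohort ROI mean-volume template.
#' @param roi_cv Within-group coefficient of variation of each ROI.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   spec including this seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 200,
                        n_patients_per_subtype = c(200, 200),
                        n_rois = 259,
                        affected_fraction = 0.4,
                        effect_size_d = 0.4,
                        n_sites = 3,
                        site_shift_sd = 150,
                        site_scale_sd = 0.1,
                        age_slope = -15,
                        sex_offset = 400,
                        prop_first_episode = 0.27,
                        prop_female = 0.6,
                        roi_mean_meanlog = log(8000),
                        roi_mean_sdlog = 0.5,
                        roi_cv = 0.12,
                        seed = 1L) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  k <- length(spec$n_patients_per_subtype)
  check <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid cohort spec: field `%s` %s.", field, msg))
  }
  check(spec$n_controls >= 1, "n_controls", "must be >= 1")
  check(k >= 1 && all(spec$n_patients_per_subtype >= 1),
        "n_patients_per_subtype", "must all be >= 1")
  check(spec$n_rois >= 1, "n_rois", "must be >= 1")
  check(spec$affected_fraction >= 0 && spec$affected_fraction <= 1,
        "affected_fraction", "must lie in [0, 1]")
  check(all(spec$effect_size_d >= 0), "effect_size_d", "must be >= 0")
  check(length(spec$effect_size_d) %in% c(1L, k),
        "effect_size_d", "must be a scalar or one value per subtype")
  check(spec$n_sites >= 1, "n_sites", "must be >= 1")
  check(spec$site_shift_sd >= 0, "site_shift_sd", "must be >= 0")
  check(spec$site_scale_sd >= 0, "site_scale_sd", "must be >= 0")
  check(spec$roi_cv > 0, "roi_cv", "must be > 0")
  check(spec$prop_first_episode >= 0 && spec$prop_first_episode <= 1,
        "prop_first_episode", "must lie in [0, 1]")
  spec
}

# Per-subtype planted reduction (Cohen's d); subtype 1 preserved when a
# scalar d is given.
subtype_effects <- function(spec) {
  k <- length(spec$n_patients_per_subtype)
  if (length(spec$effect_size_d) == 1L) {
    c(0, rep(spec$effect_size_d, k - 1L))
  } else {
    spec$effect_size_d
  }
}

#' Generate a synthetic cohort of ROI volumes
#'
#' Draws a control mean-volume template, plants subtype effects, then adds
#' site batch effects and age/sex covariate effects. Deterministic for a
#' fixed spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (control/patient), `true_subtype` (NA for controls), `site`, `age`,
#'   `sex`, `episode_type`, and one `roi_*` column per region. Ground truth
#'   (affected ROI names per subtype, planted site shifts/scales, template
#'   means and s.d.s) is attached as attribute `"ground_truth"`; retrieve it
#'   with [cohort_ground_truth()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_controls = 20,
#'   n_patients_per_subtype = c(10, 10), n_rois = 12, seed = 7))
#' dplyr::count(cohort, group, true_subtype)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  withr::local_seed(spec$seed)

  k <- length(spec$n_patients_per_subtype)
  n_pat <- sum(spec$n_patients_per_subtype)
  n <- spec$n_controls + n_pat
  roi_names <- sprintf("roi_%03d", seq_len(spec$n_rois))

  # cohort-level template: per-ROI control mean and within-group s.d.
  mu <- exp(rnorm(spec$n_rois, spec$roi_mean_meanlog, spec$roi_mean_sdlog))
  sigma <- spec$roi_cv * mu

  # affected ROIs: seeded sample without replacement, split disjointly
  # among subtypes with a planted effect
  d_by_subtype <- subtype_effects(spec)
  n_affected <- round(spec$affected_fraction * spec$n_rois)
  affected_idx <- sort(sample.int(spec$n_rois, n_affected))
  hit <- which(d_by_subtype > 0)
  affected_by_subtype <- rep(list(integer(0)), k)
  if (length(hit) > 0 && n_affected > 0) {
    chunks <- split(affected_idx, rep(seq_along(hit), length.out = n_affected))
    for (i in seq_along(hit)) affected_by_subtype[[hit[i]]] <- chunks[[i]]
  }

  subtype <- c(rep(NA_integer_, spec$n_controls),
               rep(seq_len(k), spec$n_patients_per_subtype))
  group <- ifelse(is.na(subtype), "control", "patient")
  site <- paste0("site_", sample.int(spec$n_sites, n, replace = TRUE))
  age <- runif(n, 18, 65)
  sex <- ifelse(runif(n) < spec$prop_female, "female", "male")
  episode <- ifelse(group == "patient",
                    ifelse(runif(n) < spec$prop_first_episode,
                           "first", "recurrent"),
                    NA_character_)

  # planted batch parameters: additive shift and multiplicative noise scale
  site_levels <- paste0("site_", seq_len(spec$n_sites))
  gamma <- matrix(rnorm(spec$n_sites * spec$n_rois, 0, spec$site_shift_sd),
                  spec$n_sites, spec$n_rois,
                  dimnames = list(site_levels, roi_names))
  delta <- matrix(exp(rnorm(spec$n_sites * spec$n_rois, 0, spec$site_scale_sd)),
                  spec$n_sites, spec$n_rois,
                  dimnames = list(site_levels, roi_names))

  # disease effect first, then covariates, then site batch on top
  vol <- matrix(rep(mu, each = n), n, spec$n_rois)
  for (j in seq_len(k)) {
    idx <- affected_by_subtype[[j]]
    if (length(idx) > 0) {
      rows <- which(!is.na(subtype) & subtype == j)
      vol[rows, idx] <- vol[rows, idx] -
        matrix(rep(d_by_subtype[j] * sigma[idx], each = length(rows)),
               length(rows), length(idx))
    }
  }
  age_center <- 41.5 # middle of the 18-65 adult range
  vol <- vol + spec$age_slope * (age - age_center) +
    spec$sex_offset * (sex == "male")
  eps <- matrix(rnorm(n * spec$n_rois), n, spec$n_rois) *
    matrix(rep(sigma, each = n), n, spec$n_rois)
  site_i <- match(site, site_levels)
  vol <- vol + gamma[site_i, , drop = FALSE] +
    delta[site_i, , drop = FALSE] * eps
  vol <- pmax(vol, 1) # volumes are physical quantities
  colnames(vol) <- roi_names

  out <- tibble(
    subject_id = sprintf("sub_%04d", seq_len(n)),
    group = group,
    true_subtype = subtype,
    site = site,
    age = age,
    sex = sex,
    episode_type = episode
  )
  out <- dplyr::bind_cols(out, as_tibble(vol))
  attr(out, "ground_truth") <- list(
    affected_rois = lapply(affected_by_subtype, function(i) roi_names[i]),
    d_by_subtype = d_by_subtype,
    roi_means = setNames(mu, roi_names),
    roi_sds = setNames(sigma, roi_names),
    site_shifts = gamma,
    site_scales = delta
  )
  out
}

#' Ground truth planted in a synthetic cohort
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return A list: `affected_rois` (per subtype), `d_by_subtype`,
#'   `roi_means`, `roi_sds`, `site_shifts`, `site_scales`.
#' @export
cohort_ground_truth <- function(cohort) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) {
    abort(paste("No ground-truth attribute found; was this cohort produced",
                "by generate_cohort()? (Some data-frame operations drop",
                "attributes.)"))
  }
  gt
}

#' Specify a placebo-controlled SSRI trial on the patient arm
#'
#' Baseline severity is clinician-rated HAM-D, truncated below at the
#' trial's inclusion floor; the post-treatment score is determined by a
#' per-(subtype, arm) mean percentage reduction plus individual noise.
#'
#' @param arm_probs Named allocation probabilities over the closed arm set
#'   sertraline, escitalopram, citalopram, placebo (must sum to 1). The
#'   default reflects a 359-patient prospective sample allocated
#'   116/36/98/109 to escitalopram/citalopram/sertraline/placebo.
#' @param baseline_mean,baseline_sd HAM-D baseline distribution (points).
#' @param baseline_floor Minimum baseline (inclusion criterion; draws below
#'   it are rejected and resampled, so the realized mean sits slightly above
#'   `baseline_mean`).
#' @param mean_pct_reduction Tibble with columns `subtype`, `arm`,
#'   `mean_pct`: mean percentage reduction in each subtype-by-arm cell.
#'   Defaults to [default_cell_means()].
#' @param outcome_noise_sd S.d. of individual percentage reductions around
#'   their cell mean.
#' @param seed RNG seed.
#' @return A validated list of class `trial_spec`.
#' @export
trial_spec <- function(arm_probs = c(sertraline = 98, escitalopram = 116,
                                     citalopram = 36, placebo = 109) / 359,
                       baseline_mean = 20.5,
                       baseline_sd = 4.1,
                       baseline_floor = 14,
                       mean_pct_reduction = default_cell_means(),
                       outcome_noise_sd = 25,
                       seed = 1L) {
  spec <- structure(as.list(environment()), class = "trial_spec")
  validate_trial_spec(spec)
}

trial_arms <- c("sertraline", "escitalopram", "citalopram", "placebo")

validate_trial_spec <- function(spec) {
  if (is.null(names(spec$arm_probs)) ||
      !all(names(spec$arm_probs) %in% trial_arms)) {
    abort(sprintf("Invalid trial spec: field `arm_probs` has unknown arm name(s); arms must be among %s.",
                  paste(trial_arms, collapse = ", ")))
  }
  if (abs(sum(spec$arm_probs) - 1) > 1e-8) {
    abort("Invalid trial spec: field `arm_probs` must sum to 1.")
  }
  if (spec$baseline_floor < 0) {
    abort("Invalid trial spec: field `baseline_floor` must be >= 0.")
  }
  cells <- spec$mean_pct_reduction
  assert_columns(cells, c("subtype", "arm", "mean_pct"), "`mean_pct_reduction`")
  if (!all(cells$arm %in% trial_arms)) {
    abort(sprintf("Invalid trial spec: field `mean_pct_reduction` has unknown arm name(s): %s.",
                  paste(setdiff(cells$arm, trial_arms), collapse = ", ")))
  }
  if (spec$outcome_noise_sd < 0) {
    abort("Invalid trial spec: field `outcome_noise_sd` must be >= 0.")
  }
  spec
}

#' Default subtype-by-arm mean percentage reductions
#'
#' Subtype 1 responds strongly to any SSRI (51.1%) but weakly to placebo
#' (28.6%); subtype 2 improves comparably under SSRI (46.9%) and placebo
#' (42.2%) — the treatment-relevant structure the interaction analysis is
#' designed to detect.
#'
#' @param k Number of subtypes (cells beyond 2 recycle the subtype-2 row).
#' @return A tibble with columns `subtype`, `arm`, `mean_pct`.
#' @export
default_cell_means <- function(k = 2) {
  ssri <- setdiff(trial_arms, "placebo")
  base <- dplyr::bind_rows(
    tibble(subtype = 1, arm = ssri, mean_pct = 51.1),
    tibble(subtype = 1, arm = "placebo", mean_pct = 28.6),
    tibble(subtype = 2, arm = ssri, mean_pct = 46.9),
    tibble(subtype = 2, arm = "placebo", mean_pct = 42.2)
  )
  if (k > 2) {
    extra <- purrr::map_dfr(3:k, function(j) {
      dplyr::mutate(dplyr::filter(base, .data$subtype == 2), subtype = j)
    })
    base <- dplyr::bind_rows(base, extra)
  }
  dplyr::filter(base, .data$subtype <= k)
}

#' Generate pre/post trial outcomes for the patients of a cohort
#'
#' Each patient is allocated to an arm, given a truncated-normal HAM-D
#' baseline, and a percentage reduction drawn around their
#' (subtype, arm) cell mean; the post score is
#' `round(pre * (1 - pct/100))`, clipped at 0.
#'
#' @param cohort A cohort tibble containing patients (from
#'   [generate_cohort()] or equivalent).
#' @param trial A [trial_spec()].
#' @return A tibble with one row per patient: `subject_id`, `true_subtype`,
#'   `arm`, `pre_score`, `post_score`, `pct_change` (recomputed from the
#'   final integer scores), plus `site`, `age`, `sex` carried over.
#' @export
generate_outcomes <- function(cohort, trial) {
  validate_trial_spec(trial)
  patients <- dplyr::filter(cohort, .data$group == "patient")
  if (nrow(patients) == 0L) abort("`cohort` contains no patients.")
  withr::local_seed(trial$seed)

  n <- nrow(patients)
  arm <- sample(names(trial$arm_probs), n, replace = TRUE,
                prob = trial$arm_probs)
  pre <- rnorm(n, trial$baseline_mean, trial$baseline_sd)
  while (any(pre < trial$baseline_floor)) {
    low <- pre < trial$baseline_floor
    pre[low] <- rnorm(sum(low), trial$baseline_mean, trial$baseline_sd)
  }
  pre <- round(pre)

  cells <- trial$mean_pct_reduction
  key <- paste(patients$true_subtype, arm)
  cell_mean <- cells$mean_pct[match(key, paste(cells$subtype, cells$arm))]
  if (anyNA(cell_mean)) {
    abort(sprintf("No mean_pct_reduction cell for: %s.",
                  paste(unique(key[is.na(cell_mean)]), collapse = "; ")))
  }
  pct <- rnorm(n, cell_mean, trial$outcome_noise_sd)
  post <- pmax(0, round(pre * (1 - pct / 100)))

  tibble(
    subject_id = patients$subject_id,
    true_subtype = patients$true_subtype,
    arm = arm,
    pre_score = pre,
    post_score = post,
    pct_change = percent_change(pre, post),
    site = patients$site,
    age = patients$age,
    sex = patients$sex
  )
}

#' Write / read a cohort as CSV with a JSON ground-truth sidecar
#'
#' The CSV has one row per subject and ROI columns prefixed `roi_`; the
#' sidecar records affected ROI names, per-subtype effect sizes and planted
#' site parameters so tests can score recovery.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path; the sidecar goes to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    gt$site_shifts <- as.data.frame(gt$site_shifts)
    gt$site_scales <- as.data.frame(gt$site_scales)
    jsonlite::write_json(gt, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    gt <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    gt$site_shifts <- as.matrix(gt$site_shifts)
    gt$site_scales <- as.matrix(gt$site_scales)
    attr(cohort, "ground_truth") <- gt
  }
  cohort
}
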