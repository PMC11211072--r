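test_that("percentage change follows the clinical convention exactly", {
  expect_equal(percent_change(20, 10), 50)
  expect_equal(percent_change(20, 20), 0)
  expect_equal(percent_change(20, 25), -25) # worsening is negative
  expect_error(percent_change(0, 5), "> 0")
  # inverse reconstructs post exactly, and the sign helper flips
  pre <- c(14, 20, 27)
  post <- c(3, 11, 27)
  expect_equal(post_from_change(pre, percent_change(pre, post)), post)
  expect_equal(negate_change(48.7), -48.7)
})

test_that("responder rule uses an inclusive 50% boundary", {
  expect_true(responder(51.1))
  expect_false(responder(46.9))
  expect_true(responder(50))
  expect_false(responder(49.99))
  expect_true(responder(30, threshold = 30))
})

# Noiseless balanced records with exactly the cell-mean structure the
# generator plants; covariates constant so they cannot absorb anything.
noiseless_records <- function(n_per_cell = 12) {
  cells <- tidyr::expand_grid(
    true_subtype = 1:2,
    arm = c("sertraline", "escitalopram", "citalopram", "placebo"),
    rep = seq_len(n_per_cell)
  )
  means <- default_cell_means()
  cells <- dplyr::inner_join(cells, means,
                             by = c("true_subtype" = "subtype", "arm"))
  dplyr::mutate(cells,
                subject_id = sprintf("s%04d", dplyr::row_number()),
                pct_change = mean_pct,
                age = 40, sex = "female", site = "site_1")
}

test_that("noiseless interaction equals the difference-in-differences of cell means", {
  rec <- noiseless_records()
  fit <- fit_interaction(rec, arms = "binary", covariates = character(0))
  beta <- tidy(fit)
  inter <- beta$estimate[beta$interaction]
  # (46.9 - 42.2) - (51.1 - 28.6) = -17.8
  expect_equal(inter, (46.9 - 42.2) - (51.1 - 28.6), tolerance = 1e-10)
  expect_equal(inter, -17.8, tolerance = 1e-10)
  # main effects: ssri-vs-placebo in D1, D2-vs-D1 under placebo
  expect_equal(beta$estimate[beta$term == ".treatssri"], 51.1 - 28.6,
               tolerance = 1e-10)
  expect_equal(beta$estimate[beta$term == ".dimD2"], 42.2 - 28.6,
               tolerance = 1e-10)
})

test_that("equal cell means produce a null interaction", {
  rec <- dplyr::mutate(noiseless_records(), pct_change = 40)
  fit <- fit_interaction(rec, arms = "binary", covariates = character(0))
  beta <- tidy(fit)
  expect_lt(max(abs(beta$estimate[beta$term != "(Intercept)"])), 1e-10)
})

test_that("interaction is recovered within 2 points at trial scale", {
  co <- generate_cohort(cohort_spec(n_controls = 5,
                                    n_patients_per_subtype = c(1000, 1000),
                                    n_rois = 4, seed = 71))
  oc <- generate_outcomes(co, trial_spec(outcome_noise_sd = 10, seed = 72))
  fit <- fit_interaction(oc, arms = "binary",
                         covariates = c("age", "sex", "site"))
  beta <- tidy(fit)
  expect_equal(beta$estimate[beta$interaction], -17.8, tolerance = 2 / 17.8)
  expect_true(beta$p_value[beta$interaction] < 0.05)
})

test_that("coefficients are invariant to covariate recentering", {
  co <- generate_cohort(cohort_spec(n_controls = 5,
                                    n_patients_per_subtype = c(150, 150),
                                    n_rois = 4, seed = 73))
  oc <- generate_outcomes(co, trial_spec(outcome_noise_sd = 15, seed = 74))
  f1 <- fit_interaction(oc, covariates = c("age", "sex", "site"))
  oc2 <- dplyr::mutate(oc, age = age - 40)
  f2 <- fit_interaction(oc2, covariates = c("age", "sex", "site"))
  b1 <- tidy(f1)
  b2 <- tidy(f2)
  keep <- b1$term != "(Intercept)"
  expect_equal(b1$estimate[keep], b2$estimate[keep], tolerance = 1e-10)
  # CI brackets the estimate; residual df matches the model size
  expect_true(all(b1$conf_low <= b1$estimate & b1$estimate <= b1$conf_high))
  expect_equal(f1$df_residual, f1$n - nrow(b1))
})

test_that("four-arm coding yields one interaction per drug", {
  rec <- noiseless_records()
  fit <- fit_interaction(rec, arms = "four_arm", covariates = character(0))
  beta <- tidy(fit)
  expect_equal(sum(beta$interaction), 3L)
  # all SSRIs share their subtype cell mean here, so the three
  # drug-specific interactions all equal the binary one
  expect_equal(unname(beta$estimate[beta$interaction]), rep(-17.8, 3),
               tolerance = 1e-10)
})

test_that("Cohen's f2 matches its definition and the partial-F conversion", {
  rec <- withr::with_seed(75, dplyr::mutate(
    noiseless_records(20), pct_change = pct_change + rnorm(160, 0, 20)))
  full <- fit_interaction(rec, arms = "binary", covariates = character(0))
  reduced_lm <- lm(pct_change ~ .dim + .treat, data = full$fit$model)
  reduced <- list(r_squared = summary(reduced_lm)$r.squared,
                  fit = reduced_lm)
  f2 <- cohens_f2(full, reduced)
  expect_equal(f2, (full$r_squared - reduced$r_squared) /
                 (1 - full$r_squared))
  expect_gte(f2, 0)
  # direct arithmetic example
  expect_equal(cohens_f2(list(r_squared = 0.5), list(r_squared = 0.4)), 0.2)
  expect_equal(cohens_f2(list(r_squared = 0.3), list(r_squared = 0.3)), 0)
  # internal consistency: f2 = F * df_num / df_den for the added term
  an <- anova(reduced_lm, full$fit)
  f_stat <- an$F[2]
  df_num <- an$Df[2]
  df_den <- an$Res.Df[2]
  expect_equal(f2, f_stat * df_num / df_den, tolerance = 1e-10)
})

test_that("partial-F power hits the trial's analytic claims", {
  # null effect: power collapses to the type-I rate
  expect_equal(power_partial_f(0, 359, n_extra_covariates = 6), 0.05,
               tolerance = 1e-10)
  # binary-arm spec: f2 = 0.06, n = 359, 6 extra covariates
  expect_gt(power_partial_f(0.06, 359, n_extra_covariates = 6), 0.99)
  # four-arm spec: f2 = 0.13, 10 extra covariates
  expect_gt(power_partial_f(0.13, 359, n_extra_covariates = 10), 0.99)
  # both noncentrality conventions clear the bound
  expect_gt(power_partial_f(0.06, 359, n_extra_covariates = 6,
                            lambda = "n"), 0.99)
  expect_gt(power_partial_f(0.13, 359, n_extra_covariates = 10,
                            lambda = "n"), 0.99)
})

test_that("power is monotone in effect size and sample size", {
  f2_grid <- c(0.01, 0.03, 0.06, 0.1, 0.2)
  p_f2 <- vapply(f2_grid, power_partial_f, numeric(1), n = 100)
  expect_true(all(diff(p_f2) > 0))
  n_grid <- c(30, 60, 120, 240, 480)
  p_n <- vapply(n_grid, function(n) power_partial_f(0.06, n), numeric(1))
  expect_true(all(diff(p_n) > 0))
  expect_error(power_partial_f(0.05, 5, n_extra_covariates = 6), "df")
})

test_that("distance regression reproduces categorical contrasts on coded data", {
  rec <- noiseless_records()
  # distance = -1 for D1, +1 for D2 encodes the dimension exactly;
  # slope contrasts are then half the categorical ones
  rec$distance <- ifelse(rec$true_subtype == 2, 1, -1)
  fit <- hyperplane_distance_regression(rec, arms = "binary",
                                        covariates = character(0))
  beta <- tidy(fit)
  expect_equal(beta$estimate[beta$term == "distance:.treatssri"],
               -17.8 / 2, tolerance = 1e-10)
  expect_equal(beta$estimate[beta$term == "distance"], (42.2 - 28.6) / 2,
               tolerance = 1e-10)
  rec$distance <- 0
  expect_error(hyperplane_distance_regression(rec), "zero variance")
})

test_that("shuffled distances give calibrated interaction p-values", {
  rec <- withr::with_seed(76, dplyr::mutate(
    noiseless_records(15), pct_change = pct_change + rnorm(120, 0, 15)))
  pvals <- withr::with_seed(99, vapply(1:40, function(i) {
    rec$distance <- sample(rnorm(nrow(rec)))
    fit <- hyperplane_distance_regression(rec, arms = "binary",
                                          covariates = character(0))
    beta <- tidy(fit)
    beta$p_value[grepl("^distance:", beta$term)]
  }, numeric(1)))
  # uniform-ish: no excess small p-values
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)
})

test_that("cohort-table tests reproduce the printed sex comparison", {
  # 699 controls (404 F / 295 M) vs 685 patients (439 F / 246 M)
  demo <- tibble::tibble(
    group = rep(c("control", "patient"), c(699, 685)),
    sex = c(rep(c("female", "male"), c(404, 295)),
            rep(c("female", "male"), c(439, 246))),
    age = rnorm(1384, 37, 14)
  )
  res <- cohort_table_tests(demo, continuous = "age")
  sex_p <- res$p[res$variable == "sex"]
  expect_equal(round(sex_p, 2), 0.02)
  # identical proportions: chi-square exactly 0, p = 1
  bal <- tibble::tibble(group = rep(c("a", "b"), each = 40),
                        sex = rep(c("female", "male"), 40),
                        age = rnorm(80))
  res_bal <- cohort_table_tests(bal, continuous = character(0))
  expect_equal(res_bal$statistic[1], 0, tolerance = 1e-12)
  expect_equal(res_bal$p[1], 1)
})

test_that("chi-square p agrees with an exact permutation oracle", {
  # hand-built 2x2 at a size where the asymptotic approximation is fair:
  # group A 60/60 females/males, group B 78/42
  fa_obs <- 60; n_a <- 120; n_b <- 120; fb <- 78
  df <- tibble::tibble(
    group = rep(c("a", "b"), c(n_a, n_b)),
    sex = c(rep(c("female", "male"), c(fa_obs, n_a - fa_obs)),
            rep(c("female", "male"), c(fb, n_b - fb)))
  )
  res <- cohort_table_tests(df, continuous = character(0))
  # permutation oracle: condition on the margins and enumerate the
  # chi-square statistic over all reassignments (hypergeometric law)
  f_tot <- fa_obs + fb; n <- n_a + n_b
  stat_of <- function(fa) {
    tab <- matrix(c(fa, n_a - fa, f_tot - fa, n_b - (f_tot - fa)), 2)
    suppressWarnings(unname(chisq.test(tab, correct = FALSE)$statistic))
  }
  support <- max(0, f_tot - n_b):min(f_tot, n_a)
  probs <- stats::dhyper(support, f_tot, n - f_tot, n_a)
  stats_all <- vapply(support, stat_of, numeric(1))
  p_exact <- sum(probs[stats_all >= stat_of(fa_obs) - 1e-12])
  expect_equal(res$p[1], p_exact, tolerance = 0.15)
})
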