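#' Percentage change in a depression rating
#'
#' `(pre - post) / pre * 100`: positive values are improvement
#' (symptom reduction). [post_from_change()] is the exact inverse;
#' [negate_change()] flips to the change-from-baseline sign convention some
#' reports use.
#'
#' @param pre,post Scores (pre must be > 0).
#' @param pct Percentage reduction.
#' @return Percentage (vectorized).
#' @export
#' @examples
#' percent_change(20, 10) # 50
percent_change <- function(pre, post) {
  if (any(pre <= 0)) abort("`pre` must be > 0.")
  (pre - post) / pre * 100
}

#' @rdname percent_change
#' @export
post_from_change <- function(pre, pct) {
  pre * (1 - pct / 100)
}

#' @rdname percent_change
#' @export
negate_change <- function(pct) {
  -pct
}

#' Responder classification
#'
#' @param pct_change Percentage reduction.
#' @param threshold Response threshold (inclusive), default 50%.
#' @return Logical flag(s).
#' @export
responder <- function(pct_change, threshold = 50) {
  pct_change >= threshold
}

#' Dimension-by-treatment interaction model
#'
#' Ordinary least squares with percentage change in symptom score as the
#' outcome, dimension (categorical, reference = dimension 1) and treatment
#' (reference = placebo) as predictors plus their interaction, controlling
#' for the given covariates. With `arms = "binary"` the three SSRIs
#' collapse to one treatment level; `arms = "four_arm"` keeps
#' sertraline/escitalopram/citalopram/placebo separate and fits one
#' interaction per drug.
#'
#' @param records Outcome tibble with columns `pct_change`, `arm`, and a
#'   dimension column, plus any covariates. Empty dimension-by-arm cells do
#'   not stop the fit but are flagged in the result.
#' @param arms `"binary"` or `"four_arm"`.
#' @param covariates Covariate columns (default age, sex, site).
#' @param dimension_col Column with the dimension label (default
#'   `dimension`; falls back to `true_subtype` if absent, so generator
#'   output can be modeled directly).
#' @return An object of class `interaction_fit`: tidy coefficient table
#'   with 95% CIs, the underlying `lm`, R-squared, flags.
#' @export
fit_interaction <- function(records, arms = c("binary", "four_arm"),
                            covariates = c("age", "sex", "site"),
                            dimension_col = NULL) {
  arms <- match.arg(arms)
  dimension_col <- dimension_col %||%
    if ("dimension" %in% names(records)) "dimension" else "true_subtype"
  assert_columns(records, c("pct_change", "arm", dimension_col, covariates),
                 "`records`")
  df <- as.data.frame(records)
  df$.dim <- factor(paste0("D", df[[dimension_col]]))
  if (nlevels(df$.dim) < 2L) abort("Need at least 2 dimension levels.")
  df$.treat <- if (arms == "binary") {
    factor(ifelse(df$arm == "placebo", "placebo", "ssri"),
           levels = c("placebo", "ssri"))
  } else {
    factor(df$arm,
           levels = c("placebo", "sertraline", "escitalopram", "citalopram"))
  }
  df$.treat <- droplevels(df$.treat)
  if (nlevels(df$.treat) < 2L) abort("Need at least 2 treatment levels.")
  empty_cells <- as.data.frame(table(df$.dim, df$.treat))
  empty_cells <- empty_cells[empty_cells$Freq == 0, , drop = FALSE]
  if (nrow(empty_cells) > 0) {
    warn(sprintf("Empty dimension-by-arm cell(s): %s",
                 paste(paste(empty_cells$Var1, empty_cells$Var2, sep = ":"),
                       collapse = ", ")))
  }

  rhs <- paste(c(".dim * .treat", covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste("pct_change ~", rhs)), data = df)
  interaction_fit(fit, df, flags = list(empty_cells = nrow(empty_cells) > 0),
                  terms_highlight = grep(":", names(coef(fit)), value = TRUE))
}

interaction_fit <- function(fit, data, flags = list(), terms_highlight) {
  sm <- summary(fit)
  ct <- sm$coefficients
  ci <- stats::confint(fit, level = 0.95)
  coef_tbl <- tibble(
    term = rownames(ct),
    estimate = unname(ct[, 1]),
    std_error = unname(ct[, 2]),
    conf_low = unname(ci[rownames(ct), 1]),
    conf_high = unname(ci[rownames(ct), 2]),
    statistic = unname(ct[, 3]),
    p_value = unname(ct[, 4]),
    significant = unname(ct[, 4] < 0.05),
    interaction = rownames(ct) %in% terms_highlight
  )
  structure(
    list(
      coefficients = coef_tbl,
      r_squared = sm$r.squared,
      df_residual = fit$df.residual,
      n = length(fit$residuals),
      fit = fit,
      flags = flags
    ),
    class = "interaction_fit"
  )
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Interaction model: n = %d, R^2 = %.3f, residual df = %d\n",
              x$n, x$r_squared, x$df_residual))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Cohen's f-squared of the terms distinguishing two nested fits
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`.
#'
#' @param full,reduced `interaction_fit` objects (or anything with
#'   `r_squared`); `reduced` must be nested in `full`.
#' @return Non-negative scalar (up to numerical tolerance).
#' @export
cohens_f2 <- function(full, reduced) {
  terms_of <- function(f) {
    if (!is.null(f$fit)) attr(stats::terms(f$fit), "term.labels") else NULL
  }
  tf <- terms_of(full)
  tr <- terms_of(reduced)
  if (!is.null(tf) && !is.null(tr) && !all(tr %in% tf)) {
    abort("`reduced` is not nested in `full`.")
  }
  (full$r_squared - reduced$r_squared) / (1 - full$r_squared)
}

#' Power of a partial-F test via the noncentral F distribution
#'
#' Analytic power of the F test for a regression term of effect size
#' Cohen's f2 in a model with `df_num` numerator degrees of freedom,
#' `n_main_terms` main-effect columns implied by the interaction and
#' `n_extra_covariates` further adjusted covariates:
#' `df_den = n - df_num - n_main_terms - n_extra_covariates - 1`, and the
#' noncentrality is `lambda = f2 * (df_num + df_den + 1)` (the common
#' power-software convention) or `lambda = f2 * n` under
#' `lambda = "n"`.
#'
#' @param f2 Cohen's f-squared (>= 0).
#' @param n Sample size.
#' @param df_num Numerator df of the tested term (default 1).
#' @param n_extra_covariates Additional adjusted covariate columns.
#' @param n_main_terms Main-effect columns implied by the interaction
#'   (default 2: dimension + treatment).
#' @param alpha Type-I error (two-sided threshold), default 0.05.
#' @param lambda Noncentrality convention, `"df"` or `"n"`.
#' @return Power in `[alpha, 1]`; equals `alpha` when `f2 = 0`.
#' @export
#' @examples
#' power_partial_f(0.06, 359, n_extra_covariates = 6) # > 0.99
power_partial_f <- function(f2, n, df_num = 1, n_extra_covariates = 0,
                            n_main_terms = 2, alpha = 0.05,
                            lambda = c("df", "n")) {
  lambda <- match.arg(lambda)
  if (f2 < 0) abort("`f2` must be >= 0.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  df_den <- n - df_num - n_extra_covariates - n_main_terms - 1
  if (df_den <= 0) abort("Denominator df <= 0 for this n and model size.")
  ncp <- if (lambda == "df") f2 * (df_num + df_den + 1) else f2 * n
  crit <- qf(1 - alpha, df_num, df_den)
  pf(crit, df_num, df_den, ncp = ncp, lower.tail = FALSE)
}

#' Interaction model with the hyperplane distance as a continuous exposure
#'
#' Refits the dimension-by-treatment model replacing the categorical
#' dimension with the signed hyperplane distance (positive = dimension-2
#' side), giving per-arm slopes of treatment response in the distance.
#'
#' @param records Outcome tibble with a `distance` column (join the output
#'   of [hyperplane_distance()] beforehand).
#' @inheritParams fit_interaction
#' @return An `interaction_fit`.
#' @export
hyperplane_distance_regression <- function(records,
                                           arms = c("binary", "four_arm"),
                                           covariates = c("age", "sex", "site")) {
  arms <- match.arg(arms)
  assert_columns(records, c("pct_change", "arm", "distance", covariates),
                 "`records`")
  if (anyNA(records$distance)) abort("`distance` has missing values.")
  if (var(records$distance) == 0) abort("`distance` has zero variance.")
  df <- as.data.frame(records)
  df$.treat <- if (arms == "binary") {
    factor(ifelse(df$arm == "placebo", "placebo", "ssri"),
           levels = c("placebo", "ssri"))
  } else {
    factor(df$arm,
           levels = c("placebo", "sertraline", "escitalopram", "citalopram"))
  }
  df$.treat <- droplevels(df$.treat)
  rhs <- paste(c("distance * .treat", covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste("pct_change ~", rhs)), data = df)
  interaction_fit(fit, df,
                  terms_highlight = grep(":", names(coef(fit)), value = TRUE))
}

#' Demographic-table group tests
#'
#' The standard cohort-table comparisons between two groups: chi-square
#' test of independence (no continuity correction by default) for sex, and
#' two-sided Mann-Whitney U tests for continuous variables.
#'
#' @param data Subject tibble with a grouping column, `sex`, and the
#'   continuous variables.
#' @param group_col Column defining the two comparison groups.
#' @param continuous Continuous variable columns to test (those present are
#'   used).
#' @param correct Apply Yates continuity correction to the chi-square test.
#' @return A tibble `variable`, `test`, `statistic`, `p`, `p_2sig`
#'   (p rounded to 2 significant figures, as printed in a cohort table).
#' @export
cohort_table_tests <- function(data, group_col = "group",
                               continuous = c("age", "years_education"),
                               correct = FALSE) {
  assert_columns(data, c(group_col, "sex"), "`data`")
  g <- factor(data[[group_col]])
  if (nlevels(g) != 2L) abort("`group_col` must define exactly 2 groups.")

  tab <- table(data$sex, g)
  if (any(stats::chisq.test(tab, correct = correct)$expected < 1)) {
    warn("Expected cell count < 1; consider an exact test.")
  }
  cs <- suppressWarnings(chisq.test(tab, correct = correct))
  rows <- list(tibble(variable = "sex", test = "chi-square",
                      statistic = unname(cs$statistic), p = cs$p.value))
  for (v in intersect(continuous, names(data))) {
    mw <- wilcox.test(data[[v]] ~ g, exact = FALSE)
    rows[[length(rows) + 1]] <- tibble(
      variable = v, test = "mann-whitney",
      statistic = unname(mw$statistic), p = mw$p.value
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_2sig <- signif(out$p, 2)
  out
}
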