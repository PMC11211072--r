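#' Remove covariate effects from ROI volumes
#'
#' Regresses every ROI on the covariates and returns the residuals plus the
#' ROI's grand mean, leaving group labels and all non-ROI columns
#' untouched. Rows with missing covariate or ROI values are dropped with a
#' message.
#'
#' @param data Cohort tibble.
#' @param covariates Character vector of covariate columns; empty means
#'   pass-through.
#' @return The tibble with adjusted `roi_*` columns.
#' @export
residualize <- function(data, covariates = c("age", "sex")) {
  if (length(covariates) == 0L) return(data)
  assert_columns(data, covariates, "`data`")
  rois <- roi_cols(data)
  keep <- complete.cases(data[c(covariates, rois)])
  if (!all(keep)) {
    inform(sprintf("Dropping %d row(s) with missing values.", sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  y <- roi_matrix(data)
  x <- cbind(`(Intercept)` = 1, build_cov_design(data, covariates)$x)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
    abort(sprintf("Covariate design is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(x, y)
  adj <- fit$residuals + outer(rep(1, nrow(y)), colMeans(y))
  set_roi_matrix(data, adj)
}

#' ROI-level covariate-adjusted group-difference map
#'
#' The ROI-resolution analog of a voxel-wise statistical parametric map:
#' covariates are removed per ROI with a linear model, each ROI is compared
#' between the two contrast groups with a Welch two-sample test, effects
#' are reported as signed Cohen's d (positive = larger in the first,
#' "case", group), and p-values are Benjamini-Hochberg adjusted across all
#' ROIs in the map, masking at `q < fdr`.
#'
#' Subgroup variants (a single dimension versus controls, first-episode
#' patients only, extra covariates such as education or the
#' episode-history medication proxy) are expressed by filtering or
#' relabeling `data` before the call.
#'
#' @param data Cohort tibble.
#' @param contrast Length-2 character vector of group labels: case first,
#'   reference second.
#' @param covariates Covariates removed before testing.
#' @param group_col Column holding the contrast labels (default `group`).
#' @param fdr FDR mask level.
#' @return A tibble of class `effect_map`: `roi`, `effect_d`, `p`, `q`,
#'   `significant`; contrast metadata in attributes `contrast` and `n`.
#' @export
group_difference_map <- function(data, contrast = c("patient", "control"),
                                 covariates = c("age", "sex"),
                                 group_col = "group", fdr = 0.05) {
  stopifnot(length(contrast) == 2L)
  assert_columns(data, group_col, "`data`")
  g <- data[[group_col]]
  data <- data[g %in% contrast, , drop = FALSE]
  g <- data[[group_col]]
  n1 <- sum(g == contrast[1])
  n2 <- sum(g == contrast[2])
  if (n1 < 3L || n2 < 3L) {
    abort("Each contrast group needs at least 3 subjects.")
  }
  adj <- residualize(data, covariates)
  y <- roi_matrix(adj)
  g <- adj[[group_col]]

  i1 <- g == contrast[1]
  m1 <- colMeans(y[i1, , drop = FALSE])
  m2 <- colMeans(y[!i1, , drop = FALSE])
  v1 <- apply(y[i1, , drop = FALSE], 2, var)
  v2 <- apply(y[!i1, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * pt(-abs(t_stat), df)
  s_pool <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- ifelse(s_pool > 0, (m1 - m2) / s_pool, 0)
  q <- p.adjust(p, method = "BH")

  out <- tibble(
    roi = colnames(y),
    effect_d = unname(d),
    p = unname(p),
    q = unname(q),
    significant = unname(q < fdr)
  )
  attr(out, "contrast") <- contrast
  attr(out, "covariates") <- covariates
  attr(out, "n") <- c(n1, n2)
  class(out) <- c("effect_map", class(out))
  out
}

#' Write an effect map to CSV
#'
#' @param map An `effect_map`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_effect_map <- function(map, path) {
  readr::write_csv(map, path)
  invisible(path)
}
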