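#' Fit a multi-site harmonization model for ROI volumes
#'
#' Removes additive (location) and multiplicative (scale) site batch
#' effects from ROI features using the empirical-Bayes location/scale model
#' standard for multi-site imaging features (the ComBat family): per-ROI
#' volumes are residualized on the covariates, standardized, per-site
#' shifts and scales are estimated and shrunk toward common priors (normal
#' for shifts, inverse-gamma for scales, moment-matched, solved
#' iteratively), the data are adjusted, and covariate effects are restored.
#'
#' Biological covariates listed in `preserve` (typically the diagnosis
#' group) are part of the regression design so that case-control
#' differences are not absorbed into the site terms, and their effects are
#' restored on output. The nuisance covariates in `covariates` are removed
#' along with the site effects by default — the adjustment target is
#' "site, age and sex", not site alone — but [apply_harmonization()] can
#' restore them for a site-only adjustment.
#'
#' @param data Cohort tibble with a `site` column, the covariates, and
#'   `roi_*` volume columns.
#' @param covariates Character vector of nuisance covariate columns
#'   (default age and sex).
#' @param preserve Character vector of protected biological covariates
#'   (default `"group"`).
#' @param eb Use empirical-Bayes shrinkage of the site parameters (default)
#'   or plain per-site location/scale estimates (`eb = FALSE`).
#' @return An object of class `harmonization_model`.
#' @export
fit_harmonization <- function(data, covariates = c("age", "sex"),
                              preserve = "group", eb = TRUE) {
  assert_columns(data, c("site", covariates, preserve), "`data`")
  site <- factor(data$site)
  if (nlevels(site) < 2L) {
    abort(paste("Only one site present; harmonization is undefined.",
                "Pass the data through unchanged instead."))
  }
  if (any(table(site) < 2L)) {
    abort("Every site must have at least 2 subjects.")
  }

  y <- roi_matrix(data)
  n <- nrow(y)
  p <- ncol(y)

  # constant ROIs cannot be standardized; exempt them
  constant <- apply(y, 2, function(v) var(v) == 0)
  if (any(constant)) {
    warn(sprintf("ROI(s) with zero variance exempted from harmonization: %s",
                 paste(colnames(y)[constant], collapse = ", ")))
  }
  active <- which(!constant)
  y_act <- y[, active, drop = FALSE]

  nuis_design <- build_cov_design(data, covariates)
  pres_design <- build_cov_design(data, preserve)
  batch <- stats::model.matrix(~ 0 + site)
  x <- cbind(batch, nuis_design$x, pres_design$x)
  if (qr(x)$rank < ncol(x)) {
    abort("Covariate design is rank deficient (collinear with site or each other).")
  }
  fit <- lm.fit(x, y_act)
  beta <- fit$coefficients
  n_batch <- nlevels(site)
  n_nuis <- ncol(nuis_design$x)
  gamma_hat_fit <- beta[seq_len(n_batch), , drop = FALSE]
  beta_nuis <- beta[n_batch + seq_len(n_nuis), , drop = FALSE]
  beta_pres <- beta[-seq_len(n_batch + n_nuis), , drop = FALSE]

  # grand mean: site intercepts averaged with site-size weights
  site_n <- as.vector(table(site))
  alpha <- as.vector(site_n %*% gamma_hat_fit) / n
  var_pooled <- colSums((y_act - x %*% beta)^2) / n

  stand_mean <- outer(rep(1, n), alpha) + nuis_design$x %*% beta_nuis +
    pres_design$x %*% beta_pres
  z <- (y_act - stand_mean) / outer(rep(1, n), sqrt(var_pooled))

  gamma_hat <- rowsum(z, site) / site_n
  delta2_hat <- (rowsum(z^2, site) - site_n * gamma_hat^2) / (site_n - 1)

  if (eb) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    for (s in seq_len(n_batch)) {
      sol <- eb_site_solution(z[site == levels(site)[s], , drop = FALSE],
                              gamma_hat[s, ], delta2_hat[s, ])
      gamma_star[s, ] <- sol$gamma
      delta2_star[s, ] <- sol$delta2
    }
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  structure(
    list(
      rois = colnames(y),
      active_rois = colnames(y)[active],
      site_levels = levels(site),
      covariates = covariates,
      preserve = preserve,
      nuis_info = nuis_design$info,
      pres_info = pres_design$info,
      alpha = setNames(alpha, colnames(y_act)),
      beta_nuis = beta_nuis,
      beta_pres = beta_pres,
      var_pooled = setNames(var_pooled, colnames(y_act)),
      gamma = gamma_star,
      delta2 = delta2_star,
      eb = eb
    ),
    class = "harmonization_model"
  )
}

# Iterative empirical-Bayes posterior estimates for one site, following the
# standard moment-matched normal / inverse-gamma parametric scheme.
eb_site_solution <- function(z_site, g_hat, d2_hat, tol = 1e-4,
                             max_iter = 100) {
  n_s <- nrow(z_site)
  g_bar <- mean(g_hat)
  t2 <- var(g_hat)
  m <- mean(d2_hat)
  v <- var(d2_hat)
  a_prior <- (2 * v + m^2) / v
  b_prior <- (m * v + m^3) / v
  g_old <- g_hat
  d_old <- d2_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n_s * g_hat + d_old * g_bar) / (t2 * n_s + d_old)
    sum2 <- colSums((z_site - outer(rep(1, n_s), g_new))^2)
    d_new <- (0.5 * sum2 + b_prior) / (n_s / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < tol) break
  }
  list(gamma = g_old, delta2 = d_old)
}

# Numeric covariates pass through; character/factor covariates become
# treatment dummies with levels frozen at fit time so the design is
# reproducible on new data.
build_cov_design <- function(data, cols) {
  info <- list()
  parts <- list()
  for (cl in cols) {
    v <- data[[cl]]
    if (is.numeric(v)) {
      info[[cl]] <- list(type = "numeric")
      parts[[cl]] <- matrix(v, ncol = 1, dimnames = list(NULL, cl))
    } else {
      f <- factor(v)
      info[[cl]] <- list(type = "factor", levels = levels(f))
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cl, levels(f)[-1])
        parts[[cl]] <- mm
      }
    }
  }
  x <- if (length(parts)) do.call(cbind, parts) else
    matrix(numeric(0), nrow(data), 0)
  list(x = x, info = info)
}

rebuild_cov_design <- function(data, info) {
  parts <- list()
  for (cl in names(info)) {
    v <- data[[cl]]
    if (info[[cl]]$type == "numeric") {
      parts[[cl]] <- matrix(v, ncol = 1, dimnames = list(NULL, cl))
    } else {
      lev <- info[[cl]]$levels
      if (!all(v %in% lev)) {
        abort(sprintf("Column `%s` has level(s) unseen at fit time: %s",
                      cl, paste(setdiff(unique(v), lev), collapse = ", ")))
      }
      f <- factor(v, levels = lev)
      if (length(lev) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cl, lev[-1])
        parts[[cl]] <- mm
      }
    }
  }
  if (length(parts)) do.call(cbind, parts) else
    matrix(numeric(0), nrow(data), 0)
}

#' Apply a fitted harmonization model
#'
#' Adjusts the ROI volumes of `data` using the site shifts/scales and
#' covariate coefficients of `model`; all non-ROI columns are untouched and
#' row order is preserved. Sites unseen at fit time are an error (no
#' extrapolation).
#'
#' By default the nuisance covariate effects (age, sex) are removed
#' together with the site effects, leaving only the grand mean and the
#' protected biological effects — the feature set the clustering stage
#' expects. `restore_covariates = TRUE` instead adds the nuisance effects
#' back, yielding a site-only (ComBat-style) adjustment.
#'
#' @param data Cohort tibble whose ROI set is contained in the model's.
#' @param model A `harmonization_model` from [fit_harmonization()].
#' @param restore_covariates Add the nuisance covariate effects back.
#' @return `data` with adjusted `roi_*` columns.
#' @export
apply_harmonization <- function(data, model, restore_covariates = FALSE) {
  stopifnot(inherits(model, "harmonization_model"))
  assert_columns(data, c("site", model$covariates, model$preserve), "`data`")
  rois <- roi_cols(data)
  if (!all(rois %in% model$rois)) {
    abort(sprintf("ROI(s) absent from the model: %s",
                  paste(setdiff(rois, model$rois), collapse = ", ")))
  }
  if (!all(data$site %in% model$site_levels)) {
    abort(sprintf("Site(s) unseen at fit time: %s",
                  paste(setdiff(unique(data$site), model$site_levels),
                        collapse = ", ")))
  }
  act <- intersect(rois, model$active_rois)
  if (length(act) == 0L) return(data)
  y <- as.matrix(data[act])
  n <- nrow(y)
  x_nuis <- rebuild_cov_design(data, model$nuis_info)
  x_pres <- rebuild_cov_design(data, model$pres_info)
  nuis_mean <- x_nuis %*% model$beta_nuis[, act, drop = FALSE]
  pres_mean <- x_pres %*% model$beta_pres[, act, drop = FALSE]
  stand_mean <- outer(rep(1, n), model$alpha[act]) + nuis_mean + pres_mean
  sig <- outer(rep(1, n), sqrt(model$var_pooled[act]))
  z <- (y - stand_mean) / sig
  s_i <- match(data$site, model$site_levels)
  z_adj <- (z - model$gamma[s_i, act, drop = FALSE]) /
    sqrt(model$delta2[s_i, act, drop = FALSE])
  restored <- outer(rep(1, n), model$alpha[act]) + pres_mean
  if (restore_covariates) restored <- restored + nuis_mean
  data[act] <- as.data.frame(z_adj * sig + restored)
  data
}

#' Per-ROI one-way site ANOVA F tests
#'
#' Diagnostic used before/after harmonization: for each ROI, the p-value of
#' a one-way ANOVA of volume on site.
#'
#' @param data Cohort tibble with `site` and `roi_*` columns.
#' @return A tibble `roi`, `f`, `p`.
#' @export
site_effect_tests <- function(data) {
  y <- roi_matrix(data)
  site <- factor(data$site)
  n <- nrow(y)
  k <- nlevels(site)
  site_n <- as.vector(table(site))
  grand <- colMeans(y)
  means <- rowsum(y, site) / site_n
  ss_between <- colSums(site_n * (means - outer(rep(1, k), grand))^2)
  ss_within <- colSums((y - means[as.integer(site), , drop = FALSE])^2)
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  tibble(
    roi = colnames(y),
    f = f,
    p = pf(f, k - 1, n - k, lower.tail = FALSE)
  )
}

#' Serialize / restore a harmonization model as JSON
#'
#' @param model A `harmonization_model`.
#' @param path File path.
#' @return `path` invisibly; `read_harmonization()` returns the model.
#' @export
write_harmonization <- function(model, path) {
  out <- model
  out$beta_nuis <- as.data.frame(out$beta_nuis)
  out$beta_pres <- as.data.frame(out$beta_pres)
  out$gamma <- as.data.frame(out$gamma)
  out$delta2 <- as.data.frame(out$delta2)
  # named vectors must go out as objects or the names are lost
  out$alpha <- as.list(out$alpha)
  out$var_pooled <- as.list(out$var_pooled)
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_harmonization
#' @export
read_harmonization <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$beta_nuis <- as.matrix(raw$beta_nuis)
  raw$beta_pres <- as.matrix(raw$beta_pres)
  raw$gamma <- as.matrix(raw$gamma)
  raw$delta2 <- as.matrix(raw$delta2)
  raw$alpha <- unlist(raw$alpha)
  raw$var_pooled <- unlist(raw$var_pooled)
  structure(raw, class = "harmonization_model")
}
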