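#' Percentage overlap of two dimension assignments
#'
#' Compares two labelings over the patients they share after
#' maximum-overlap label alignment, so the statistic is invariant to global
#' relabeling of either analysis.
#'
#' @param assign,reference Named integer vectors (names = subject ids,
#'   values = dimension labels).
#' @param k Number of dimensions.
#' @return Percentage in `[0, 100]` of shared patients assigned to the same
#'   dimension.
#' @export
assignment_overlap <- function(assign, reference, k = max(assign, reference)) {
  shared <- intersect(names(assign), names(reference))
  if (length(shared) == 0L) abort("No shared subjects to compare.")
  a <- assign[shared]
  r <- reference[shared]
  perm <- align_labels(a, r, k = k)
  100 * mean(perm[a] == r)
}

model_assignments <- function(model) {
  setNames(model$assignments$dimension, model$assignments$subject_id)
}

#' Split-sample replication of the dimension analysis
#'
#' Splits the cohort into halves stratified jointly by group, site, sex and
#' age tertile (falling back to site-only strata, with a warning, if the
#' joint strata are too sparse), runs the full dimension-selection and
#' consensus pipeline independently on each half, and reports whether both
#' halves choose the same number of dimensions together with the agreement
#' of their dimension-versus-control effect-map sign patterns.
#'
#' @param data Cohort tibble.
#' @param k_range,n_subsamples,restarts,max_iter,cost Passed to
#'   [select_k()] within each half.
#' @param covariates Covariates for the per-half effect maps.
#' @param seed RNG seed (controls the split and both half-pipelines).
#' @return A list of class `stability_report` with `protocol =
#'   "split_sample"`: per-half chosen k, assignments, split balance
#'   statistics, and the aligned effect-map sign-agreement fractions.
#' @export
split_sample <- function(data, k_range = 2:5, n_subsamples = 10,
                         restarts = 1, max_iter = 30, cost = 4,
                         covariates = c("age", "sex"), seed = 1L) {
  strata <- interaction(data$group, data$site, data$sex,
                        dplyr::ntile(data$age, 3), drop = TRUE)
  if (stats::median(table(strata)) < 2) {
    warn("Joint strata too sparse; falling back to site-only stratification.")
    strata <- interaction(data$group, data$site, drop = TRUE)
  }
  half <- withr::with_seed(child_seed(seed, 1), {
    h <- integer(nrow(data))
    for (s in levels(strata)) {
      idx <- which(strata == s)
      idx <- sample(idx)
      h[idx] <- rep(1:2, length.out = length(idx))
    }
    h
  })

  halves <- lapply(1:2, function(i) data[half == i, , drop = FALSE])
  fits <- lapply(1:2, function(i) {
    rep_i <- select_k(halves[[i]], k_range = k_range,
                      n_subsamples = n_subsamples, restarts = restarts,
                      max_iter = max_iter, cost = cost,
                      seed = child_seed(seed, 10 + i))
    list(report = rep_i, model = consensus_assign(rep_i))
  })

  sign_agreement <- effect_sign_agreement(halves, fits, covariates)

  structure(
    list(
      protocol = "split_sample",
      chosen_k = vapply(fits, function(f) f$report$chosen_k, numeric(1)),
      same_k = fits[[1]]$report$chosen_k == fits[[2]]$report$chosen_k,
      assignments = lapply(fits, function(f) model_assignments(f$model)),
      stability = lapply(fits, function(f) f$report$stability),
      balance = split_balance(halves),
      effect_sign_agreement = sign_agreement,
      half = half
    ),
    class = "stability_report"
  )
}

split_balance <- function(halves) {
  tibble(
    half = 1:2,
    n = vapply(halves, nrow, numeric(1)),
    mean_age = vapply(halves, function(h) mean(h$age), numeric(1)),
    prop_female = vapply(halves, function(h) mean(h$sex == "female"),
                         numeric(1))
  )
}

# Mean signed dimension-vs-control effects per half, dimensions aligned
# across halves by best-correlation matching; returns per-dimension
# fraction of ROIs whose effect signs agree.
effect_sign_agreement <- function(halves, fits, covariates) {
  k1 <- fits[[1]]$report$chosen_k
  k2 <- fits[[2]]$report$chosen_k
  if (k1 != k2) return(NULL)
  eff <- lapply(1:2, function(i) {
    h <- halves[[i]]
    lab <- model_assignments(fits[[i]]$model)
    sapply(seq_len(k1), function(d) {
      ids <- names(lab)[lab == d]
      sub <- dplyr::filter(h, .data$group == "control" |
                             .data$subject_id %in% ids)
      group_difference_map(sub, covariates = covariates)$effect_d
    })
  })
  perms <- permutations(k1)
  score <- vapply(perms, function(p) {
    sum(vapply(seq_len(k1), function(d) {
      stats::cor(eff[[1]][, d], eff[[2]][, p[d]])
    }, numeric(1)))
  }, numeric(1))
  p <- perms[[which.max(score)]]
  vapply(seq_len(k1), function(d) {
    mean(sign(eff[[1]][, d]) == sign(eff[[2]][, p[d]]))
  }, numeric(1))
}

#' Leave-site-out robustness of the dimension assignments
#'
#' For each acquisition site, refits the model on all subjects except that
#' site and reports the percentage of retained patients assigned to the
#' same dimension as a full-sample reference model, after label alignment.
#' By default k is fixed at the reference model's k; with `reselect_k =
#' TRUE` the k-range scan is re-run per fold, and a fold that chooses a
#' different k is recorded with an undefined overlap and flagged.
#'
#' @param data Cohort tibble (>= 3 sites).
#' @param reference A full-sample `hydra_model`.
#' @param reselect_k Re-run dimension selection inside each fold.
#' @param k_range,n_subsamples Used only when `reselect_k = TRUE`.
#' @param restarts,max_iter,cost Fitting settings per fold.
#' @param seed RNG seed.
#' @return A list of class `stability_report` with `protocol =
#'   "leave_site_out"`: per-site tibble (`site`, `k_used`, `n_shared`,
#'   `overlap_pct`, `flagged`) and the overlap min/mean/max.
#' @export
leave_site_out <- function(data, reference, reselect_k = FALSE,
                           k_range = 2:5, n_subsamples = 10, restarts = 2,
                           max_iter = 30, cost = 4, seed = 1L) {
  sites <- sort(unique(data$site))
  if (length(sites) < 3L) abort("Leave-site-out needs at least 3 sites.")
  ref_assign <- model_assignments(reference)

  rows <- purrr::map_dfr(seq_along(sites), function(i) {
    s <- sites[i]
    kept <- dplyr::filter(data, .data$site != s)
    if (reselect_k) {
      rep_s <- select_k(kept, k_range = k_range,
                        n_subsamples = n_subsamples, restarts = restarts,
                        max_iter = max_iter, cost = cost,
                        seed = child_seed(seed, i))
      k_used <- rep_s$chosen_k
      if (k_used != reference$k) {
        return(tibble(site = s, k_used = k_used, n_shared = NA_integer_,
                      overlap_pct = NA_real_, flagged = TRUE))
      }
      fit <- consensus_assign(rep_s)
    } else {
      k_used <- reference$k
      fit <- fit_hydra(kept, reference$k, cost = cost,
                       n_restarts = restarts, max_iter = max_iter,
                       seed = child_seed(seed, i))
    }
    a <- model_assignments(fit)
    shared <- intersect(names(a), names(ref_assign))
    tibble(
      site = s, k_used = k_used, n_shared = length(shared),
      overlap_pct = assignment_overlap(a, ref_assign, k = reference$k),
      flagged = FALSE
    )
  })

  ok <- rows$overlap_pct[!rows$flagged]
  structure(
    list(
      protocol = "leave_site_out",
      per_site = rows,
      overlap_min = min(ok),
      overlap_mean = mean(ok),
      overlap_max = max(ok)
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability protocol:", x$protocol, "\n")
  if (x$protocol == "leave_site_out") {
    print(x$per_site)
    cat(sprintf("overlap %% min/mean/max: %.2f / %.2f / %.2f\n",
                x$overlap_min, x$overlap_mean, x$overlap_max))
  } else {
    cat("chosen k per half:", x$chosen_k,
        if (x$same_k) "(agree)" else "(disagree)", "\n")
    print(x$balance)
    if (!is.null(x$effect_sign_agreement)) {
      cat("effect-map sign agreement per dimension:",
          round(x$effect_sign_agreement, 3), "\n")
    }
  }
  invisible(x)
}
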