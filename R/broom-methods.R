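# broom-style accessors so every fitted object drops into a dplyr chain.

#' Tidy a HYDRA model into its patient assignments
#'
#' @param x A `hydra_model`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `dimension`.
#' @method tidy hydra_model
#' @export
tidy.hydra_model <- function(x, ...) {
  x$assignments
}

#' @rdname tidy.hydra_model
#' @method glance hydra_model
#' @export
glance.hydra_model <- function(x, ...) {
  tibble(
    k = x$k,
    n_patients = nrow(x$assignments),
    n_rois = length(x$rois),
    objective = x$objective,
    converged = x$converged,
    stability_ari = x$stability_ari %||% NA_real_
  )
}

#' Tidy a dimension-selection report
#'
#' @param x A `model_selection_report`.
#' @param ... Unused.
#' @return The per-k stability tibble.
#' @method tidy model_selection_report
#' @export
tidy.model_selection_report <- function(x, ...) {
  x$stability
}

#' @rdname tidy.model_selection_report
#' @method glance model_selection_report
#' @export
glance.model_selection_report <- function(x, ...) {
  tibble(
    chosen_k = x$chosen_k,
    best_stability_ari = max(x$stability$stability_ari),
    no_reliable_dimensions = x$no_reliable_dimensions
  )
}

#' Tidy an interaction-model fit
#'
#' @param x An `interaction_fit`.
#' @param ... Unused.
#' @return The coefficient tibble (estimate, SE, 95% CI, p).
#' @method tidy interaction_fit
#' @export
tidy.interaction_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.interaction_fit
#' @method glance interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    df_residual = x$df_residual,
    n = x$n,
    empty_cells = isTRUE(x$flags$empty_cells)
  )
}

#' Tidy a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return Leave-site-out: the per-site overlap tibble. Split-sample: the
#'   per-half balance tibble with chosen k.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  if (x$protocol == "leave_site_out") {
    x$per_site
  } else {
    dplyr::mutate(x$balance, chosen_k = x$chosen_k)
  }
}

#' @rdname tidy.stability_report
#' @method glance stability_report
#' @export
glance.stability_report <- function(x, ...) {
  if (x$protocol == "leave_site_out") {
    tibble(protocol = x$protocol, overlap_min = x$overlap_min,
           overlap_mean = x$overlap_mean, overlap_max = x$overlap_max)
  } else {
    tibble(protocol = x$protocol, same_k = x$same_k,
           chosen_k_1 = x$chosen_k[1], chosen_k_2 = x$chosen_k[2])
  }
}
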