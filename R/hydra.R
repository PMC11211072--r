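#' Fit a HYDRA-style semi-supervised clustering model
#'
#' Partitions patients into `k` neuroanatomical dimensions, each separated
#' from the shared healthy-control group by its own soft-margin linear SVM
#' (a "1-to-k" mapping). The fit alternates between (i) training one
#' classifier per dimension (controls labelled -1, that dimension's
#' patients +1, class-balanced weights) and (ii) reassigning every patient
#' to the hyperplane with the largest normalized signed score
#' `(w.x + b)/||w||` (ties to the lowest dimension index), until
#' assignments are unchanged or `max_iter` sweeps. The first restart is
#' seeded by k-means on the patient features; further restarts use random
#' assignments. The restart with the best (lowest) regularized hinge
#' objective wins.
#'
#' Features are z-scored per ROI against control statistics before
#' clustering so hyperplane coefficients are comparable across regions.
#'
#' @param data Cohort tibble with `subject_id`, `group`
#'   (control/patient) and `roi_*` columns.
#' @param k Number of dimensions (`k = 1` reduces to a single
#'   patients-vs-controls classifier).
#' @param cost Soft-margin penalty budget of each linear SVM: the total
#'   hinge weight available to a subproblem, spread over its expected
#'   number of observations (so the effective per-observation penalty
#'   shrinks as cohorts grow and the fit does not overfit spurious
#'   separations of the preserved dimension from controls).
#' @param n_restarts Number of initializations.
#' @param max_iter Maximum alternating sweeps per restart.
#' @param seed RNG seed (initializations and k-means are derived from it).
#' @param init Optional initial assignment: integer vector in `1..k` named
#'   by patient `subject_id` (used by [consensus_assign()]); when supplied,
#'   it becomes the single initialization.
#' @return An object of class `hydra_model`: hyperplanes (`w` p-by-k
#'   matrix, `b` offsets), `assignments` tibble (`subject_id`,
#'   `dimension`), the per-iteration objective trace of the winning
#'   restart, convergence flag, and the control z-scoring statistics.
#' @export
fit_hydra <- function(data, k, cost = 4, n_restarts = 10, max_iter = 50,
                      seed = 1L, init = NULL,
                      init_method = c("kmeans", "random")) {
  init_method <- match.arg(init_method)
  if (k < 1) abort("`k` must be >= 1.")
  assert_columns(data, c("subject_id", "group"), "`data`")
  x <- roi_matrix(data)
  if (!all(is.finite(x))) abort("ROI features must be finite.")
  is_pat <- data$group == "patient"
  if (sum(!is_pat) == 0L) abort("`data` contains no controls.")
  if (sum(is_pat) < k) abort("Fewer patients than dimensions `k`.")

  mu <- colMeans(x[!is_pat, , drop = FALSE])
  sd_c <- apply(x[!is_pat, , drop = FALSE], 2, sd)
  sd_c[sd_c == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd_c, "/")
  zc <- z[!is_pat, , drop = FALSE]
  zp <- z[is_pat, , drop = FALSE]
  pat_ids <- data$subject_id[is_pat]
  n_pat <- nrow(zp)

  # Per-observation penalties: `cost` is a total hinge budget spread over
  # the expected subproblem size (controls + n_p/k patients), so the
  # regularization strength is invariant to cohort size; the patient class
  # is up-weighted to balance the larger control group. Both are fixed
  # across iterations so the recorded objective is the exact quantity the
  # alternation decreases.
  w_ctrl <- cost / (nrow(zc) + n_pat / k)
  w_pat <- w_ctrl * max(1, nrow(zc) / max(1, n_pat / k))

  withr::local_seed(seed)
  inits <- list()
  if (!is.null(init)) {
    init <- init[pat_ids]
    if (anyNA(init) || !all(init %in% seq_len(k))) {
      abort("`init` must label every patient with a dimension in 1..k.")
    }
    inits[[1]] <- as.integer(init)
  } else {
    random_init <- function() {
      a <- sample.int(k, n_pat, replace = TRUE)
      a[sample.int(n_pat, k)] <- seq_len(k) # every dimension inhabited
      a
    }
    inits[[1]] <- if (k == 1L) {
      rep(1L, n_pat)
    } else if (init_method == "kmeans") {
      km <- suppressWarnings(kmeans(zp, centers = k, nstart = 3))
      as.integer(km$cluster)
    } else {
      random_init()
    }
    if (n_restarts > 1) {
      for (r in 2:n_restarts) inits[[r]] <- random_init()
    }
  }

  best <- NULL
  for (r in seq_along(inits)) {
    res <- hydra_alternate(zc, zp, k, inits[[r]], cost, w_ctrl, w_pat,
                           max_iter)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (!best$converged) {
    warn("HYDRA did not converge within `max_iter`; returning best iterate.")
  }

  structure(
    list(
      k = k,
      w = best$w,
      b = best$b,
      assignments = tibble(subject_id = pat_ids,
                           dimension = best$assign),
      objective = best$objective,
      objective_trace = best$trace,
      converged = best$converged,
      cost = cost,
      center = mu,
      scale = sd_c,
      rois = colnames(x),
      seed = seed
    ),
    class = "hydra_model"
  )
}

# One alternating run from a given initialization. Objective: sum over
# hyperplanes of 0.5*||w||^2 + per-class penalties * hinge losses.
hydra_alternate <- function(zc, zp, k, assign, cost, w_ctrl, w_pat,
                            max_iter) {
  n_pat <- nrow(zp)
  p <- ncol(zp)
  trace <- numeric(0)
  converged <- FALSE
  w <- matrix(0, p, k)
  b <- numeric(k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      rows <- which(assign == j)
      hp <- fit_margin_classifier(zc, zp[rows, , drop = FALSE],
                                  weights = c(w_ctrl, w_pat))
      w[, j] <- hp$w
      b[j] <- hp$b
    }
    trace <- c(trace, hydra_objective(zc, zp, assign, w, b, w_ctrl, w_pat))

    norms <- sqrt(colSums(w^2))
    norms[norms == 0] <- 1
    scores <- sweep(zp %*% w + outer(rep(1, n_pat), b), 2, norms, "/")
    new_assign <- max.col(scores, ties.method = "first")
    # empty-dimension rule: reseed with the patient farthest below all
    # current hyperplanes
    empty <- setdiff(seq_len(k), unique(new_assign))
    if (length(empty) > 0) {
      far <- order(apply(scores, 1, max))
      used <- integer(0)
      for (j in empty) {
        cand <- setdiff(far, used)[1]
        new_assign[cand] <- j
        used <- c(used, cand)
      }
    }
    if (all(new_assign == assign)) {
      converged <- TRUE
      break
    }
    assign <- new_assign
  }
  list(w = w, b = b, assign = assign, objective = trace[length(trace)],
       trace = trace, converged = converged)
}

# Soft-margin linear SVM: controls (-1) vs one dimension's patients (+1).
# `weights` are absolute per-observation hinge penalties per class; the
# default splits a total budget of `cost` evenly between the classes
# (class-balanced). Inside the HYDRA alternation the weights are instead
# frozen at the design ratio (controls vs expected subgroup size n_p/k) so
# the alternation minimizes one fixed objective. Returns w, b oriented so
# patients score positive.
fit_margin_classifier <- function(z_neg, z_pos, cost = 1, weights = NULL) {
  xx <- rbind(z_neg, z_pos)
  yy <- factor(rep(c(-1L, 1L), c(nrow(z_neg), nrow(z_pos))),
               levels = c(-1L, 1L))
  cw <- if (is.null(weights)) {
    c("-1" = cost / (2 * nrow(z_neg)), "1" = cost / (2 * nrow(z_pos)))
  } else {
    c("-1" = weights[1], "1" = weights[2])
  }
  m <- e1071::svm(xx, yy, kernel = "linear", scale = FALSE, cost = 1,
                  class.weights = cw)
  w <- as.vector(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # orient: mean patient score above mean control score
  if (mean(z_pos %*% w + b) < mean(z_neg %*% w + b)) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

hydra_objective <- function(zc, zp, assign, w, b, w_ctrl, w_pat) {
  k <- ncol(w)
  obj <- 0
  fc <- zc %*% w + outer(rep(1, nrow(zc)), b)
  fp <- zp %*% w + outer(rep(1, nrow(zp)), b)
  for (j in seq_len(k)) {
    rows <- which(assign == j)
    obj <- obj + 0.5 * sum(w[, j]^2) +
      w_ctrl * sum(pmax(0, 1 + fc[, j])) +
      w_pat * sum(pmax(0, 1 - fp[rows, j]))
  }
  obj
}

z_transform <- function(model, data) {
  x <- roi_matrix(data)[, model$rois, drop = FALSE]
  sweep(sweep(x, 2, model$center), 2, model$scale, "/")
}

#' Select the number of dimensions by ARI stability
#'
#' For each candidate `k`, HYDRA is refit on seeded subsamples of the
#' patients (controls always fully included) and the stability is the mean
#' pairwise adjusted Rand index of the assignments over the patients two
#' subsamples share. The chosen `k` maximizes mean stability; ties go to
#' the smallest `k`. If no `k` reaches `reliable_min`, the report carries a
#' `no_reliable_dimensions` flag.
#'
#' @param data Cohort tibble (controls + patients).
#' @param k_range Candidate dimension counts, default `2:5`.
#' @param n_subsamples Number of seeded subsamples per `k` (>= 2).
#' @param subsample_frac Fraction of patients kept per subsample.
#' @param restarts,max_iter,cost Passed to [fit_hydra()] for the resampled
#'   fits (fewer restarts than a final fit; the stability scan averages
#'   over many fits already).
#' @param reliable_min Stability below which no dimension structure is
#'   declared reliable.
#' @param seed RNG seed.
#' @return An object of class `model_selection_report`: `stability` tibble
#'   (`k`, `stability_ari`, `n_pairs`), `chosen_k`,
#'   `no_reliable_dimensions`, and the archived per-subsample assignments.
#' @export
select_k <- function(data, k_range = 2:5, n_subsamples = 20,
                     subsample_frac = 0.9, restarts = 2, max_iter = 30,
                     cost = 4, reliable_min = 0.3, seed = 1L,
                     init_method = c("kmeans", "random")) {
  init_method <- match.arg(init_method)
  if (length(k_range) == 0L) abort("`k_range` must be non-empty.")
  if (n_subsamples < 2L) {
    abort("Stability is undefined for fewer than 2 subsamples.")
  }
  is_pat <- data$group == "patient"
  n_pat <- sum(is_pat)
  n_keep <- max(2L, floor(subsample_frac * n_pat))
  controls <- dplyr::filter(data, .data$group == "control")
  patients <- dplyr::filter(data, .data$group == "patient")

  archive <- list()
  stability <- purrr::map_dfr(k_range, function(k) {
    runs <- lapply(seq_len(n_subsamples), function(r) {
      s <- child_seed(seed, 1000 * k + r)
      idx <- withr::with_seed(s, sample.int(n_pat, n_keep))
      sub <- dplyr::bind_rows(controls, patients[idx, ])
      fit <- fit_hydra(sub, k, cost = cost, n_restarts = restarts,
                       max_iter = max_iter, seed = s,
                       init_method = init_method)
      setNames(fit$assignments$dimension, fit$assignments$subject_id)
    })
    archive[[as.character(k)]] <<- runs
    pairs <- utils::combn(n_subsamples, 2)
    aris <- apply(pairs, 2, function(pr) {
      a <- runs[[pr[1]]]
      b <- runs[[pr[2]]]
      shared <- intersect(names(a), names(b))
      adjusted_rand_index(a[shared], b[shared])
    })
    tibble(k = k, stability_ari = mean(aris), n_pairs = ncol(pairs))
  })

  best <- max(stability$stability_ari)
  chosen <- min(stability$k[stability$stability_ari == best])
  structure(
    list(
      stability = stability,
      chosen_k = chosen,
      no_reliable_dimensions = best < reliable_min,
      reliable_min = reliable_min,
      iterations = archive,
      data = data,
      params = list(n_subsamples = n_subsamples,
                    subsample_frac = subsample_frac, restarts = restarts,
                    max_iter = max_iter, cost = cost, seed = seed,
                    init_method = init_method)
    ),
    class = "model_selection_report"
  )
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("Dimension selection by ARI stability\n")
  print(x$stability)
  cat("chosen k:", x$chosen_k,
      if (x$no_reliable_dimensions) "(no reliable dimensions)" else "", "\n")
  invisible(x)
}

#' Consensus dimension assignment across stability iterations
#'
#' Aligns the archived subsample assignments at `k` to a common labeling by
#' maximum-overlap matching, takes a per-patient majority vote, builds the
#' patient-by-patient co-assignment (consensus) matrix, and refits HYDRA on
#' the full sample initialized from the consensus labels to obtain the
#' reported hyperplanes.
#'
#' @param report A `model_selection_report` from [select_k()].
#' @param k Dimension count (default the report's chosen k).
#' @return A `hydra_model` with extra fields `consensus` (matrix) and
#'   `stability_ari`.
#' @export
consensus_assign <- function(report, k = report$chosen_k) {
  runs <- report$iterations[[as.character(k)]]
  if (is.null(runs) || length(runs) < 2L) {
    abort(sprintf("Report holds fewer than 2 iterations at k = %d.", k))
  }
  ids <- unique(unlist(lapply(runs, names)))
  pat_ids <- dplyr::filter(report$data, .data$group == "patient")$subject_id
  orphan <- setdiff(pat_ids, ids)
  if (length(orphan) > 0) {
    abort(sprintf("Subject(s) absent from every iteration: %s",
                  paste(head(orphan, 5), collapse = ", ")))
  }

  ref <- runs[[1]]
  aligned <- lapply(runs, function(a) {
    shared <- intersect(names(a), names(ref))
    perm <- align_labels(a[shared], ref[shared], k = k)
    setNames(perm[a], names(a))
  })

  votes <- matrix(0L, length(ids), k, dimnames = list(ids, NULL))
  for (a in aligned) {
    pos <- cbind(match(names(a), ids), a)
    votes[pos] <- votes[pos] + 1L
  }
  consensus_label <- max.col(votes, ties.method = "first")
  names(consensus_label) <- ids

  n_both <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  n_same <- n_both
  for (a in aligned) {
    present <- names(a)
    n_both[present, present] <- n_both[present, present] + 1
    same <- outer(a, a, "==")
    n_same[present, present] <- n_same[present, present] + same
  }
  consensus <- ifelse(n_both > 0, n_same / n_both, NA_real_)
  diag(consensus) <- 1

  final <- fit_hydra(report$data, k,
                     cost = report$params$cost,
                     n_restarts = 1,
                     max_iter = report$params$max_iter,
                     seed = child_seed(report$params$seed, 999),
                     init = consensus_label[pat_ids])
  # the reported labels are the consensus votes; the refit contributes the
  # hyperplanes (its own converged assignment is kept for reference)
  final$refit_assignments <- final$assignments
  final$assignments <- tibble(subject_id = pat_ids,
                              dimension = unname(consensus_label[pat_ids]))
  final$consensus <- consensus
  final$stability_ari <-
    report$stability$stability_ari[report$stability$k == k]
  final
}

#' Signed distance from the dimension-separating hyperplane
#'
#' For a two-dimension model, trains a linear max-margin classifier
#' separating dimension-1 from dimension-2 patients and returns each
#' patient's signed, norm-scaled distance from that boundary. Positive
#' values lie on the dimension-2 side; larger magnitudes mean more certain
#' assignment.
#'
#' @param model A `hydra_model` with `k = 2`.
#' @param data Cohort tibble containing the model's patients (defaults to
#'   assigning over the patients the model was fit on when it stores no
#'   data; pass the cohort explicitly).
#' @param cost SVM penalty for the separating classifier.
#' @return A tibble `subject_id`, `dimension`, `distance`.
#' @export
hyperplane_distance <- function(model, data, cost = 1) {
  if (model$k != 2L) abort("Hyperplane distance is defined for k = 2 models.")
  z <- z_transform(model, data)
  lab <- model$assignments
  idx <- match(lab$subject_id, data$subject_id)
  if (anyNA(idx)) abort("`data` is missing patients present in the model.")
  z_pat <- z[idx, , drop = FALSE]
  d1 <- z_pat[lab$dimension == 1L, , drop = FALSE]
  d2 <- z_pat[lab$dimension == 2L, , drop = FALSE]
  if (nrow(d1) == 0L || nrow(d2) == 0L) {
    abort("Both dimensions must contain patients.")
  }
  hp <- fit_margin_classifier(d1, d2, cost) # positive side = dimension 2
  nrm <- sqrt(sum(hp$w^2))
  if (nrm == 0) abort("Degenerate separating hyperplane (zero weights).")
  tibble(
    subject_id = lab$subject_id,
    dimension = lab$dimension,
    distance = as.vector(z_pat %*% hp$w + hp$b) / nrm
  )
}

#' @export
print.hydra_model <- function(x, ...) {
  cat(sprintf("HYDRA model: k = %d, %d patients, %d ROIs\n",
              x$k, nrow(x$assignments), length(x$rois)))
  print(dplyr::count(x$assignments, .data$dimension))
  if (!is.null(x$stability_ari)) {
    cat(sprintf("stability ARI: %.3f\n", x$stability_ari))
  }
  invisible(x)
}

#' Serialize a HYDRA model (JSON) and its assignments (CSV)
#'
#' @param model A `hydra_model`.
#' @param path JSON path; assignments go to `<path base>.assignments.csv`.
#' @return `path` invisibly.
#' @export
write_hydra <- function(model, path) {
  out <- model
  out$w <- as.data.frame(out$w)
  out$consensus <- NULL # large and reconstructible; keep the JSON light
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA)
  readr::write_csv(model$assignments,
                   paste0(sub("\\.json$", "", path), ".assignments.csv"))
  invisible(path)
}
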