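# Internal helpers shared across modules.

#' Derive a child seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through this fixed
#' affine map so that a stage run inside the pipeline and the same stage run
#' standalone with the derived seed produce identical output. Results stay
#' below 2^31 so they are always valid R integer seeds.
#'
#' @param seed Integer global seed.
#' @param offset Integer stage offset (each stage uses a distinct one).
#' @return An integer seed.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), is.numeric(offset))
  as.integer((abs(seed) + 100003 * (offset + 1)) %% .Machine$integer.max)
}

# Names of the ROI-volume columns of a cohort tibble (prefix "roi_").
roi_cols <- function(data) {
  grep("^roi_", names(data), value = TRUE)
}

# Extract the ROI matrix (subjects x ROIs) from a cohort tibble.
roi_matrix <- function(data) {
  rois <- roi_cols(data)
  if (length(rois) == 0L) {
    abort("`data` contains no ROI columns (expected columns prefixed 'roi_').")
  }
  m <- as.matrix(data[rois])
  rownames(m) <- data$subject_id
  m
}

# Replace the ROI columns of a cohort tibble with the columns of `m`
# (same order, same subjects).
set_roi_matrix <- function(data, m) {
  stopifnot(nrow(m) == nrow(data))
  data[colnames(m)] <- as.data.frame(m)
  data
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Enumerate all permutations of seq_len(k); k is small (<= 5) everywhere
# this is used, so factorial growth is not a concern.
permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Maximum-overlap label alignment: returns the permutation `perm` such that
# relabelling `labels` as perm[labels] maximises agreement with `reference`.
# Exact assignment solve by enumeration over the k! permutations (k <= 5).
align_labels <- function(labels, reference, k = max(labels, reference)) {
  conf <- matrix(0L, k, k)
  for (i in seq_along(labels)) {
    conf[labels[i], reference[i]] <- conf[labels[i], reference[i]] + 1L
  }
  best <- NULL
  best_score <- -1L
  for (p in permutations(k)) {
    score <- sum(conf[cbind(seq_len(k), p)])
    if (score > best_score) {
      best_score <- score
      best <- p
    }
  }
  unlist(best)
}
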