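# Shared fixtures and independent oracles used across the suite.

# Brute-force Rand index by explicit pair enumeration (independent of the
# contingency-table path in the package).
ri_brute <- function(p1, p2) {
  n <- length(p1)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- p1[i] == p1[j]
      s2 <- p2[i] == p2[j]
      if (s1 == s2) agree <- agree + 1
    }
  }
  agree / choose(n, 2)
}

# Brute-force Hubert-Arabie ARI from pair counts alone.
ari_brute <- function(p1, p2) {
  n <- length(p1)
  idx <- 0; e1 <- 0; e2 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- p1[i] == p1[j]
      s2 <- p2[i] == p2[j]
      if (s1 && s2) idx <- idx + 1
      if (s1) e1 <- e1 + 1
      if (s2) e2 <- e2 + 1
    }
  }
  total <- choose(n, 2)
  expected <- e1 * e2 / total
  maxi <- (e1 + e2) / 2
  if (maxi == expected) return(1)
  (idx - expected) / (maxi - expected)
}

# All set partitions of n items into at most max_k blocks, as canonical
# label vectors (restricted growth strings).
all_partitions <- function(n, max_k = 3) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    m <- max(labels)
    for (lab in seq_len(min(m + 1, max_k))) grow(c(labels, lab))
  }
  grow(1L)
  out
}

# A compact two-subtype cohort for fast fitting tests: subtype 1 preserved,
# subtype 2 reduced.
small_cohort <- function(seed = 11, d = 1.2, n_rois = 24, n_sites = 2,
                         n_controls = 50, n_per_subtype = c(30, 30),
                         site_shift_sd = 100, site_scale_sd = 0.05) {
  generate_cohort(cohort_spec(
    n_controls = n_controls, n_patients_per_subtype = n_per_subtype,
    n_rois = n_rois, affected_fraction = 0.4, effect_size_d = d,
    n_sites = n_sites, site_shift_sd = site_shift_sd,
    site_scale_sd = site_scale_sd, seed = seed
  ))
}

true_labels <- function(cohort) {
  pat <- dplyr::filter(cohort, group == "patient")
  stats::setNames(pat$true_subtype, pat$subject_id)
}
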