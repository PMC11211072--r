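test_that("k = 1 degenerates to a single patients-vs-controls classifier", {
  co <- small_cohort(seed = 4, n_controls = 40, n_per_subtype = c(20, 20),
                     n_rois = 12)
  m <- fit_hydra(co, 1, n_restarts = 1, seed = 1)
  expect_equal(m$k, 1L)
  expect_true(all(m$assignments$dimension == 1L))
  expect_equal(dim(m$w), c(12L, 1L))
  expect_error(fit_hydra(co, 0), ">= 1")
  expect_error(fit_hydra(co, 1000), "Fewer patients")
})

test_that("widely separated patient clouds are recovered almost perfectly", {
  # two subtypes reduced d = 2 on disjoint ROI sets, controls in between
  co <- generate_cohort(cohort_spec(
    n_controls = 60, n_patients_per_subtype = c(40, 40), n_rois = 24,
    affected_fraction = 0.5, effect_size_d = c(2, 2), n_sites = 2,
    seed = 8
  ))
  coh <- apply_harmonization(co, fit_harmonization(co))
  m <- fit_hydra(coh, 2, n_restarts = 3, seed = 2)
  expect_gte(adjusted_rand_index(model_assignments(m), true_labels(co)),
             0.95)
})

test_that("fits are deterministic in the seed and label all dimensions", {
  co <- small_cohort(seed = 14, n_controls = 40, n_per_subtype = c(25, 25),
                     n_rois = 15)
  m1 <- fit_hydra(co, 3, n_restarts = 2, seed = 5)
  m2 <- fit_hydra(co, 3, n_restarts = 2, seed = 5)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$w, m2$w)
  # the empty-dimension reseeding rule keeps every dimension inhabited
  expect_setequal(unique(m1$assignments$dimension), 1:3)
})

test_that("duplicated patients receive identical dimension labels", {
  co <- small_cohort(seed = 6, n_controls = 30, n_per_subtype = c(15, 15),
                     n_rois = 10)
  pat <- dplyr::filter(co, group == "patient")
  dup <- dplyr::mutate(pat, subject_id = paste0(subject_id, "_copy"))
  co2 <- dplyr::bind_rows(co, dup)
  m <- fit_hydra(co2, 2, n_restarts = 1, seed = 3)
  a <- model_assignments(m)
  expect_identical(unname(a[pat$subject_id]),
                   unname(a[paste0(pat$subject_id, "_copy")]))
})

test_that("the margin objective is monotone non-increasing across sweeps", {
  for (s in 1:5) {
    co <- small_cohort(seed = s, d = 0.5, n_controls = 50,
                       n_per_subtype = c(30, 30), n_rois = 20)
    m <- fit_hydra(co, 3, n_restarts = 2, seed = s)
    tr <- m$objective_trace
    if (length(tr) > 1) {
      rel_increase <- diff(tr) / abs(tr[-length(tr)])
      expect_lt(max(rel_increase), 1e-3)
    }
  }
})

test_that("assignment accuracy rises with the planted effect size", {
  # preserved + reduced subtype at increasing depth; mean over seeds
  mean_ari <- vapply(c(0.2, 0.5, 1.0), function(d) {
    aris <- vapply(1:4, function(s) {
      co <- generate_cohort(cohort_spec(
        n_controls = 120, n_patients_per_subtype = c(80, 80), n_rois = 100,
        effect_size_d = d, n_sites = 2, seed = 300 + s
      ))
      coh <- apply_harmonization(co, fit_harmonization(co))
      m <- suppressWarnings(fit_hydra(coh, 2, n_restarts = 1, seed = s,
                                      max_iter = 25))
      adjusted_rand_index(model_assignments(m), true_labels(co))
    }, numeric(1))
    mean(aris)
  }, numeric(1))
  expect_true(all(diff(mean_ari) > 0))
})

test_that("dimension selection needs >= 2 subsamples and stays in range", {
  co <- small_cohort(seed = 9, n_controls = 40, n_per_subtype = c(20, 20),
                     n_rois = 12)
  expect_error(select_k(co, n_subsamples = 1), "2 subsamples")
  r <- suppressWarnings(select_k(co, k_range = 2:3, n_subsamples = 3,
                                 restarts = 1, max_iter = 15, seed = 2))
  expect_true(r$chosen_k %in% 2:3)
  expect_equal(r$stability$k, 2:3)
  expect_true(all(r$stability$stability_ari <= 1))
})

test_that("consensus assignment aligns permuted labels and votes by majority", {
  co <- small_cohort(seed = 10, n_controls = 30, n_per_subtype = c(12, 12),
                     n_rois = 10)
  pat_ids <- dplyr::filter(co, group == "patient")$subject_id
  base <- stats::setNames(rep(1:2, length.out = length(pat_ids)), pat_ids)
  flipped <- stats::setNames(3L - base, pat_ids)
  outlier <- base
  outlier[1] <- 3L - outlier[1] # one deviant vote for the first subject
  fake_report <- structure(
    list(
      iterations = list(`2` = list(base, flipped, outlier)),
      chosen_k = 2,
      stability = tibble::tibble(k = 2, stability_ari = 1, n_pairs = 3),
      data = co,
      params = list(cost = 4, max_iter = 20, seed = 1)
    ),
    class = "model_selection_report"
  )
  m <- consensus_assign(fake_report, k = 2)
  a <- model_assignments(m)
  # majority (2 of 3 aligned votes) recovers the base labeling everywhere
  expect_gte(assignment_overlap(a, base, k = 2), 100 * (1 - 1e-9))
  # perfectly agreeing iterations (up to relabeling) give a 0/1 consensus
  expect_true(all(m$consensus[pat_ids[-1], pat_ids[-1]] %in% c(0, 1)))
})

test_that("hyperplane distance separates the dimensions with the right sign", {
  co <- generate_cohort(cohort_spec(
    n_controls = 60, n_patients_per_subtype = c(40, 40), n_rois = 24,
    affected_fraction = 0.5, effect_size_d = c(2, 2), n_sites = 2, seed = 8
  ))
  coh <- apply_harmonization(co, fit_harmonization(co))
  m <- fit_hydra(coh, 2, n_restarts = 2, seed = 1)
  d <- hyperplane_distance(m, coh)
  agree <- mean(sign(d$distance) == ifelse(d$dimension == 2, 1, -1))
  expect_gte(agree, 0.95)
  # positive side is dimension 2 by convention
  expect_gt(mean(d$distance[d$dimension == 2]), 0)
  expect_lt(mean(d$distance[d$dimension == 1]), 0)
  m3 <- fit_hydra(coh, 3, n_restarts = 1, seed = 1)
  expect_error(hyperplane_distance(m3, coh), "k = 2")
})

test_that("distances are invariant to a global rescaling of the volumes", {
  co <- small_cohort(seed = 12, n_controls = 40, n_per_subtype = c(20, 20),
                     n_rois = 12, d = 1.5)
  m1 <- fit_hydra(co, 2, n_restarts = 1, seed = 7)
  co_scaled <- set_roi_matrix(co, roi_matrix(co) * 3)
  m2 <- fit_hydra(co_scaled, 2, n_restarts = 1, seed = 7)
  # control z-scoring absorbs the scale: identical assignments + distances
  expect_identical(m1$assignments, m2$assignments)
  d1 <- hyperplane_distance(m1, co)
  d2 <- hyperplane_distance(m2, co_scaled)
  expect_equal(d1$distance, d2$distance, tolerance = 1e-6)
})

test_that("unstructured patients yield low stability and a reliability flag", {
  # patients drawn from the control distribution at the native ROI count:
  # no k should look stable, and the report should say so
  co <- generate_cohort(cohort_spec(
    n_controls = 200, n_patients_per_subtype = c(200, 200), n_rois = 259,
    effect_size_d = 0, n_sites = 3, seed = 999
  ))
  coh <- apply_harmonization(co, fit_harmonization(co))
  r <- suppressWarnings(select_k(coh, k_range = 2:3, n_subsamples = 5,
                                 restarts = 1, max_iter = 20, seed = 1))
  expect_true(all(r$stability$stability_ari < 0.3))
  expect_true(r$no_reliable_dimensions)
})
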