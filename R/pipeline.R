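#' Configure an end-to-end dimension-analysis run
#'
#' Collects stage toggles and tuning parameters for [run_pipeline()]. A
#' single global `seed` fans out to per-stage seeds through [child_seed()]
#' (stage offsets: cohort 1, trial 2, model selection 3, stability 4+), so
#' a stage run standalone with the derived seed reproduces its in-pipeline
#' output.
#'
#' @param out_dir Run directory for all artifacts.
#' @param seed Global integer seed.
#' @param cohort A [cohort_spec()] to simulate, or a path to a cohort CSV.
#' @param trial A [trial_spec()] for outcome simulation, or `NULL` to skip
#'   the trial stage.
#' @param harmonize Run the site-harmonization stage (default on).
#' @param k_range Candidate dimension counts.
#' @param n_subsamples,restarts,max_iter,cost Model-selection settings.
#' @param fdr FDR level of the effect maps.
#' @param arms Interaction-model arm coding.
#' @param do_split,do_lso Run split-sample / leave-site-out protocols.
#' @param stability_subsamples Subsamples per half/fold in the protocols.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            cohort = cohort_spec(),
                            trial = trial_spec(),
                            harmonize = TRUE,
                            k_range = 2:5,
                            n_subsamples = 10,
                            restarts = 2,
                            max_iter = 30,
                            cost = 4,
                            fdr = 0.05,
                            arms = "binary",
                            do_split = FALSE,
                            do_lso = FALSE,
                            stability_subsamples = 5) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (length(cfg$k_range) == 0L || any(diff(cfg$k_range) <= 0) ||
      any(cfg$k_range < 1)) {
    abort("Invalid config: `k_range` must be an increasing range of k >= 1.")
  }
  if (cfg$n_subsamples < 2) {
    abort("Invalid config: `n_subsamples` must be >= 2.")
  }
  if (!cfg$arms %in% c("binary", "four_arm")) {
    abort("Invalid config: `arms` must be 'binary' or 'four_arm'.")
  }
  if (!inherits(cfg$cohort, "cohort_spec") && !is.character(cfg$cohort)) {
    abort("Invalid config: `cohort` must be a cohort_spec or a CSV path.")
  }
  cfg
}

#' A small demonstration configuration
#'
#' A compact synthetic cohort (preserved + reduced subtype, 3 sites) sized
#' so the full pipeline completes in well under a minute.
#'
#' @param out_dir Run directory.
#' @param seed Global seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(out_dir = tempfile("neurodim_run_"), seed = 17L) {
  pipeline_config(
    out_dir = out_dir,
    seed = seed,
    cohort = cohort_spec(n_controls = 60, n_patients_per_subtype = c(40, 40),
                         n_rois = 30, effect_size_d = 1.2, n_sites = 3),
    trial = trial_spec(outcome_noise_sd = 15),
    k_range = 2:3,
    n_subsamples = 4,
    restarts = 1,
    max_iter = 15
  )
}

#' Run the full neuroanatomical-dimension pipeline
#'
#' Executes simulate (optional) -> harmonize -> dimension selection ->
#' consensus assignment -> stability protocols (optional) -> effect maps ->
#' outcome statistics, writing every artifact under the configured run
#' directory together with a manifest of the seed, a config hash and
#' artifact checksums. Identical config + seed yields byte-identical
#' assignment artifacts and manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @return A run-report list (invisibly also written as
#'   `report.json`): chosen k, stability summaries, artifact paths.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  artifacts <- character(0)

  # --- cohort ---------------------------------------------------------
  if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    spec$seed <- child_seed(config$seed, 1)
    cohort <- generate_cohort(spec)
    write_cohort(cohort, pth("cohort.csv"))
    artifacts <- c(artifacts, "cohort.csv", "cohort.csv.truth.json")
  } else {
    cohort <- read_cohort(config$cohort)
  }

  # --- harmonization --------------------------------------------------
  if (isTRUE(config$harmonize) && length(unique(cohort$site)) >= 2) {
    hmodel <- fit_harmonization(cohort)
    cohort_h <- apply_harmonization(cohort, hmodel)
    write_harmonization(hmodel, pth("harmonization.json"))
    readr::write_csv(cohort_h, pth("harmonized.csv"), na = "")
    artifacts <- c(artifacts, "harmonization.json", "harmonized.csv")
  } else {
    cohort_h <- cohort
  }

  # --- dimension selection + consensus --------------------------------
  report <- select_k(cohort_h, k_range = config$k_range,
                     n_subsamples = config$n_subsamples,
                     restarts = config$restarts,
                     max_iter = config$max_iter, cost = config$cost,
                     seed = child_seed(config$seed, 3))
  model <- consensus_assign(report)
  write_hydra(model, pth("model.json"))
  artifacts <- c(artifacts, "model.json", "model.assignments.csv")

  # --- stability protocols --------------------------------------------
  stability_out <- list()
  if (isTRUE(config$do_split)) {
    stability_out$split <- split_sample(
      cohort_h, k_range = config$k_range,
      n_subsamples = config$stability_subsamples,
      restarts = config$restarts, max_iter = config$max_iter,
      cost = config$cost, seed = child_seed(config$seed, 4))
  }
  if (isTRUE(config$do_lso) && length(unique(cohort_h$site)) >= 3) {
    stability_out$lso <- leave_site_out(
      cohort_h, model, restarts = config$restarts,
      max_iter = config$max_iter, cost = config$cost,
      seed = child_seed(config$seed, 5))
  }

  # --- effect maps ----------------------------------------------------
  lab <- model_assignments(model)
  cohort_lab <- dplyr::mutate(
    cohort_h,
    contrast_group = dplyr::case_when(
      .data$group == "control" ~ "control",
      TRUE ~ paste0("D", lab[.data$subject_id])
    )
  )
  maps <- list(patient = group_difference_map(cohort_h, fdr = config$fdr))
  for (d in seq_len(model$k)) {
    maps[[paste0("D", d)]] <- group_difference_map(
      cohort_lab, contrast = c(paste0("D", d), "control"),
      group_col = "contrast_group", fdr = config$fdr)
  }
  for (nm in names(maps)) {
    write_effect_map(maps[[nm]], pth(sprintf("effect_map_%s.csv", nm)))
    artifacts <- c(artifacts, sprintf("effect_map_%s.csv", nm))
  }

  # --- outcome statistics ---------------------------------------------
  outcome_out <- NULL
  if (!is.null(config$trial)) {
    trial <- config$trial
    trial$seed <- child_seed(config$seed, 2)
    outcomes <- generate_outcomes(cohort, trial)
    outcomes$dimension <- lab[outcomes$subject_id]
    if (model$k == 2L) {
      dist <- hyperplane_distance(model, cohort_h)
      outcomes <- dplyr::left_join(outcomes,
                                   dist[c("subject_id", "distance")],
                                   by = "subject_id")
    }
    readr::write_csv(outcomes, pth("outcomes.csv"), na = "")
    artifacts <- c(artifacts, "outcomes.csv")
    ifit <- fit_interaction(outcomes, arms = config$arms)
    outcome_out <- list(
      interaction = tidy(ifit),
      r_squared = ifit$r_squared,
      n = ifit$n
    )
    if (model$k == 2L && var(outcomes$distance) > 0) {
      outcome_out$distance_regression <-
        tidy(hyperplane_distance_regression(outcomes, arms = config$arms))
    }
  }

  demo_tests <- cohort_table_tests(cohort, continuous = "age")

  # --- manifest + report ----------------------------------------------
  cfg_json <- pth("config.json")
  cfg_out <- config
  cfg_out$cohort <- unclass(cfg_out$cohort)
  cfg_out$trial <- if (!is.null(cfg_out$trial)) {
    t <- unclass(cfg_out$trial)
    t$mean_pct_reduction <- as.data.frame(t$mean_pct_reduction)
    t
  }
  jsonlite::write_json(unclass(cfg_out), cfg_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  # hash the config without its output location, and key artifact
  # checksums by relative name, so identical config+seed runs in
  # different directories produce identical manifests
  cfg_hash_json <- tempfile(fileext = ".json")
  cfg_out$out_dir <- NULL
  jsonlite::write_json(unclass(cfg_out), cfg_hash_json, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_hash_json)),
    artifact_md5 = as.list(setNames(
      unname(tools::md5sum(file.path(config$out_dir, artifacts))),
      artifacts)),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE)

  report_out <- list(
    chosen_k = report$chosen_k,
    stability = report$stability,
    no_reliable_dimensions = report$no_reliable_dimensions,
    dimension_sizes = as.list(table(lab)),
    lso = if (!is.null(stability_out$lso)) {
      stability_out$lso[c("overlap_min", "overlap_mean", "overlap_max")]
    },
    split_same_k = if (!is.null(stability_out$split)) {
      stability_out$split$same_k
    },
    n_significant_rois = vapply(maps, function(m) sum(m$significant),
                                numeric(1)),
    outcomes = outcome_out,
    demographics = demo_tests,
    artifacts = artifacts,
    out_dir = config$out_dir
  )
  jsonlite::write_json(report_out, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  report_out
}

#' Write / read a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly: cohort and trial specs are
#' flattened to plain lists and revalidated on read.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_pipeline_config()` returns the
#'   validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  if (inherits(out$cohort, "cohort_spec")) {
    out$cohort <- unclass(out$cohort)
  }
  if (!is.null(out$trial)) {
    out$trial <- unclass(out$trial)
    # named atomic vectors must be maps in YAML or the names are lost
    out$trial$arm_probs <- as.list(out$trial$arm_probs)
    out$trial$mean_pct_reduction <-
      as.data.frame(out$trial$mean_pct_reduction)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.list(raw$cohort)) {
    raw$cohort <- validate_cohort_spec(structure(raw$cohort,
                                                 class = "cohort_spec"))
  }
  if (!is.null(raw$trial)) {
    raw$trial$arm_probs <- unlist(raw$trial$arm_probs)
    raw$trial$mean_pct_reduction <-
      tibble::as_tibble(as.data.frame(
        lapply(raw$trial$mean_pct_reduction, unlist)))
    raw$trial <- validate_trial_spec(structure(raw$trial,
                                               class = "trial_spec"))
  }
  raw$k_range <- unlist(raw$k_range)
  validate_pipeline_config(structure(raw, class = "pipeline_config"))
}
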