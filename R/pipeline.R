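#' Pipeline configuration
#'
#' Validated bundle of all knobs for the end-to-end synthetic experiment:
#' cohort sizes, phantom calibration, the parameter sets to extract
#' (`"all21"` or a vector of compact set names), the reference set for
#' robustness and model evaluation, bootstrap/CV settings and one master
#' seed from which all randomness is derived (subject seeds and replicate
#' seeds are offsets of it).
#'
#' @param n_explore,n_test exploration and test cohort sizes.
#' @param positive_fraction fraction of denervated subjects.
#' @param spec baseline [phantom_spec()] for the exploration cohort; the
#'   test cohort uses the same calibration on a coarser native grid
#'   (0.795 x 0.795 x 2.03 mm), emulating a second scanner.
#' @param sets `"all21"` or a character vector of set names.
#' @param reference reference set name (must be among `sets`).
#' @param n_boot,folds,top_k bootstrap replicates, CV folds, simplified
#'   model size.
#' @param seed master integer seed.
#' @param fraction isocontour fraction.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_explore = 200L, n_test = 100L,
                            positive_fraction = 0.39,
                            spec = phantom_spec(),
                            sets = c("64-1-111", "32-5-111", "64-5-111"),
                            reference = NULL,
                            n_boot = 100L, folds = 5L, top_k = 3L,
                            seed = 1L, fraction = 0.40) {
  grid <- parameter_grid()
  if (identical(sets, "all21")) sets <- grid$name
  if (!all(sets %in% grid$name)) {
    abort(sprintf("Unknown set name(s): %s",
                  paste(setdiff(sets, grid$name), collapse = ", ")))
  }
  if (is.null(reference)) {
    reference <- if ("64-5-111" %in% sets) "64-5-111" else sets[length(sets)]
  }
  if (!reference %in% sets) abort("`reference` must be one of `sets`.")
  structure(
    list(n_explore = as.integer(n_explore), n_test = as.integer(n_test),
         positive_fraction = positive_fraction, spec = spec, sets = sets,
         reference = reference, n_boot = as.integer(n_boot),
         folds = as.integer(folds), top_k = as.integer(top_k),
         seed = as.integer(seed), fraction = fraction),
    class = "pipeline_config"
  )
}

stage_done <- function(paths) all(file.exists(paths))

#' Run the end-to-end synthetic experiment
#'
#' Chains the five stages -- simulate (phantom cohorts), extract (feature
#' tables per parameter set), robustness (CCC report and averaged
#' correlation matrix), select (bootstrap-LASSO per set for the
#' all-features and conventional-features series, plus the
#' probability/coefficient ranking on the reference set) and evaluate
#' (simplified model trained on the exploration set, tested on the test
#' set with independent standardisation). Every artefact is written under
#' `out_dir` and carries the config hash and seed in `run_info.json`.
#' Stages whose output files already exist are reloaded, not recomputed,
#' so an interrupted run resumes from the last completed stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the main results: feature tables,
#'   `ccc`, `cor_matrix`, `scores` (Table-3-style grid), `ranking`,
#'   `top_features`, `model` and `evaluation`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config_hash = rlang::hash(config), seed = config$seed,
         sets = config$sets, reference = config$reference,
         n_boot = config$n_boot, score_mode = "oob"),
    file.path(out_dir, "run_info.json"), auto_unbox = TRUE
  )
  grid <- parameter_grid()
  sets_tbl <- grid[grid$name %in% config$sets, ]

  # --- simulate + extract (volumes are regenerated only when needed) ----
  table_path <- function(tag, nm) {
    file.path(out_dir, sprintf("features_%s_%s.csv", tag, nm))
  }
  explore_paths <- vapply(config$sets, function(nm) table_path("explore", nm), "")
  test_path <- table_path("test", config$reference)
  if (!stage_done(c(explore_paths, test_path))) {
    explore <- generate_cohort(config$n_explore, config$positive_fraction,
                               config$spec, seed = config$seed)
    readr::write_csv(cohort_manifest(explore),
                     file.path(out_dir, "manifest_explore.csv"))
    tabs <- extract_all_sets(explore, sets_tbl, config$fraction)
    for (nm in names(tabs)) readr::write_csv(tabs[[nm]], table_path("explore", nm))
    rm(explore)
    test_spec <- phantom_spec(
      grid_shape = config$spec$grid_shape,
      voxel_spacing_mm = c(0.795, 0.795, 2.03),
      background_suv = config$spec$background_suv,
      striatal_peak_suv = config$spec$striatal_peak_suv,
      psf_fwhm_mm = config$spec$psf_fwhm_mm,
      noise_sd = config$spec$noise_sd
    )
    test <- generate_cohort(config$n_test, config$positive_fraction,
                            test_spec, seed = config$seed + 10000L)
    readr::write_csv(cohort_manifest(test),
                     file.path(out_dir, "manifest_test.csv"))
    ref_row <- sets_tbl[sets_tbl$name == config$reference, ]
    test_tab <- extract_all_sets(test, ref_row, config$fraction)[[1]]
    readr::write_csv(test_tab, test_path)
    rm(test)
  }
  tabs <- lapply(setNames(config$sets, config$sets), function(nm) {
    readr::read_csv(table_path("explore", nm), show_col_types = FALSE)
  })
  test_tab <- readr::read_csv(test_path, show_col_types = FALSE)

  # --- robustness -------------------------------------------------------
  rep_ccc <- ccc_report(tabs, reference = config$reference)
  readr::write_csv(as_tibble(rep_ccc), file.path(out_dir, "ccc_report.csv"))
  jsonlite::write_json(
    c(as.list(glance(rep_ccc)),
      list(poor_features = tidy(rep_ccc)$feature[tidy(rep_ccc)$poor])),
    file.path(out_dir, "ccc_summary.json"), auto_unbox = TRUE
  )
  cm <- averaged_correlation_matrix(tabs)
  readr::write_csv(tidy(cm), file.path(out_dir, "correlation_matrix.csv"))

  # --- select -----------------------------------------------------------
  scores <- list(); results <- list()
  for (nm in config$sets) {
    std <- standardize(tabs[[nm]])
    conv <- std[, c("subject_id", "label",
                    intersect(conventional_features(), names(std)))]
    for (series in c("conventional", "all_features")) {
      tab_in <- if (series == "conventional") conv else std
      res <- bootstrap_lasso(tab_in, n_boot = config$n_boot,
                             folds = config$folds, seed = config$seed)
      scores[[paste(nm, series)]] <- tibble(
        set = nm, series = series,
        mean_auroc = res$auroc_mean, sd_auroc = res$auroc_sd
      )
      if (series == "all_features") results[[nm]] <- res
    }
  }
  score_grid <- dplyr::bind_rows(scores)
  readr::write_csv(score_grid, file.path(out_dir, "model_scores.csv"))
  ranking <- tidy(results[[config$reference]])
  readr::write_csv(ranking, file.path(out_dir, "feature_ranking.csv"))
  top <- rank_features(results[[config$reference]], config$top_k)

  # --- evaluate ---------------------------------------------------------
  std_explore <- standardize(tabs[[config$reference]])
  std_test <- standardize(test_tab)  # independent test-set moments
  model <- fit_simplified(std_explore, top)
  eval_rep <- evaluate_model(model, std_test)
  jsonlite::write_json(
    list(features = model$features,
         coefficients = as.list(model$coefficients),
         evaluation = as.list(eval_rep)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    tables = tabs, test_table = test_tab, ccc = rep_ccc, cor_matrix = cm,
    scores = score_grid, ranking = ranking, top_features = top,
    model = model, evaluation = eval_rep
  ))
}
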