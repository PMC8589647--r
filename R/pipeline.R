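#' Run the full brain-age study on one cohort
#'
#' Executes the analysis chain on a (typically simulated) cohort:
#' hemisphere averaging, outlier QC, site-stratified train/test
#' partition, sex-specific ridge model training, pooled test-side
#' prediction, and the site-aware case-control mixed model. Stage seeds
#' are derived from the configuration seed by fixed offsets so stages
#' are individually reproducible.
#'
#' @param config A [sim_config()] object.
#' @param lambda Ridge penalty.
#' @param bin_width_years Age-bin width for the stratified split.
#' @param qc_z Outlier threshold in within-sex SD units.
#' @param folds Cross-validation folds (used when `cv = TRUE`).
#' @param cv Also run k-fold CV on each training sample.
#' @param bias_correct Apply the linear age-bias correction to test-side
#'   predictions, with the bias estimated from training-control CV
#'   predictions per sex (see [estimate_age_bias()]). Raw predictions are
#'   kept in `brain_age_raw`; CV metrics always refer to the raw model.
#' @param importance Also compute structure coefficients, modality
#'   perturbations, and single-modality comparisons.
#' @param subgroups Also run the clinical-subgroup analyses.
#' @return List with `cohort`, `features` (averaged, post-QC),
#'   `qc_report`, `split`, `models`, `cv` (per sex), `predictions`
#'   (pooled test side), `case_control`, and optionally `importance`,
#'   `subgroups`.
#' @export
run_study <- function(config, lambda = 6.5, bin_width_years = 5, qc_z = 6,
                      folds = 10, cv = FALSE, bias_correct = TRUE,
                      importance = FALSE, subgroups = FALSE) {
  sim <- generate_cohort(config)
  avg <- average_hemispheres(sim$features)
  sex <- sim$cohort$sex[match(avg$participant_id,
                              sim$cohort$participant_id)]
  qc <- qc_outliers(avg, sex, qc_z)
  feats <- qc$features
  cohort <- sim$cohort[sim$cohort$participant_id %in%
                         feats$participant_id, ]

  split <- split_controls(cohort, seed = config$seed + 101L,
                          bin_width_years = bin_width_years)
  role <- stats::setNames(split$role, split$participant_id)

  models <- list()
  cvres <- list()
  preds <- list()
  for (sx in c("male", "female")) {
    ids_tr <- split$participant_id[split$role == "train" &
      cohort$sex[match(split$participant_id, cohort$participant_id)] == sx]
    ids_te <- split$participant_id[split$role == "test" &
      cohort$sex[match(split$participant_id, cohort$participant_id)] == sx]
    if (length(ids_tr) == 0) next
    xtr <- feats[match(ids_tr, feats$participant_id), ]
    age_tr <- cohort$age[match(ids_tr, cohort$participant_id)]
    m <- fit_brainage_model(xtr, age_tr, lambda, sex = sx)
    models[[sx]] <- m
    if (cv || bias_correct)
      cvres[[sx]] <- crossvalidate_brainage(xtr, age_tr, lambda, folds,
                                            seed = config$seed + 202L,
                                            sex = sx)
    if (length(ids_te)) {
      xte <- feats[match(ids_te, feats$participant_id), ]
      age_te <- cohort$age[match(ids_te, cohort$participant_id)]
      p <- predict_brainage(m, xte, age = age_te)
      if (bias_correct)
        p <- apply_age_bias_correction(
          p, estimate_age_bias(cvres[[sx]]$predictions))
      preds[[sx]] <- p
    }
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  predictions$role <- "test"

  cc <- analyze_case_control(predictions, cohort)

  out <- list(cohort = cohort, features = feats, qc_report = qc$report,
              split = split, models = models, cv = cvres,
              predictions = predictions, case_control = cc)

  if (importance) {
    test_ids <- predictions$participant_id
    test_feats <- feats[match(test_ids, feats$participant_id), ]
    grp <- cohort$dx[match(test_ids, cohort$participant_id)]
    sc <- structure_coefficients(predictions, test_feats, grp)
    pert <- pooled_perturbation(models, feats, cohort, split)
    smm <- list()
    for (sx in names(models)) {
      ids_tr <- intersect(
        split$participant_id[split$role == "train"],
        cohort$participant_id[cohort$sex == sx])
      ids_te <- intersect(
        split$participant_id[split$role == "test"],
        cohort$participant_id[cohort$sex == sx & cohort$dx == "control"])
      smm[[sx]] <- single_modality_models(
        feats[match(ids_tr, feats$participant_id), ],
        cohort$age[match(ids_tr, cohort$participant_id)],
        feats[match(ids_te, feats$participant_id), ],
        cohort$age[match(ids_te, cohort$participant_id)],
        lambda = lambda, folds = folds, seed = config$seed + 303L)
      smm[[sx]]$sex <- sx
    }
    out$importance <- list(structure_coefficients = sc,
                           perturbation = pert,
                           single_modality = do.call(rbind, smm))
  }
  if (subgroups)
    out$subgroups <- analyze_subgroups(predictions, cohort)
  out
}

# Perturbation deltas pooled over the sex-specific models, weighting each
# sex by its test-sample size.
pooled_perturbation <- function(models, feats, cohort, split) {
  mods <- c("none", "thickness", "surface_area", "subcortical_volume")
  rows <- list()
  for (m in mods) {
    num <- 0; den <- 0; before <- 0; after <- 0
    for (sx in names(models)) {
      ids <- intersect(split$participant_id[split$role == "test"],
                       cohort$participant_id[cohort$sex == sx])
      if (!length(ids)) next
      x <- feats[match(ids, feats$participant_id), ]
      ages <- cohort$age[match(ids, cohort$participant_id)]
      p <- perturb_modality(models[[sx]], x, ages, m)
      w <- length(ids)
      num <- num + w * p$delta_mae
      before <- before + w * p$mae_before
      after <- after + w * p$mae_after
      den <- den + w
    }
    rows[[m]] <- data.frame(modality = m, mae_before = before / den,
                            mae_after = after / den,
                            delta_mae = num / den, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Run the end-to-end pipeline from a configuration file
#'
#' Reads a YAML (or JSON) configuration, simulates the cohort, runs QC,
#' partition, training, prediction, inference and interpretation, and
#' writes all tables as CSV plus a run manifest as JSON into `out_dir`.
#' Re-running with an identical configuration reproduces identical
#' numerics.
#'
#' Recognized configuration fields (all optional): `scale`, `delta_mdd`,
#' `noise_multiplier`, `bio_age_sd`, `seed`, `lambda`,
#' `bin_width_years`, `qc_z`, `folds`, `importance`, `subgroups`,
#' `sensitivity_age_range`.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of the configuration seed.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  opts <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(opts))
  if (!is.null(seed)) opts$seed <- seed
  cfg <- sim_config(
    site_specs = default_site_specs(opts$scale %||% 1),
    delta_mdd = opts$delta_mdd %||% 1.08,
    noise_multiplier = opts$noise_multiplier %||% 1.0,
    bio_age_sd = opts$bio_age_sd %||% 6.0,
    seed = opts$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  res <- run_study(cfg,
                   lambda = opts$lambda %||% 6.5,
                   bin_width_years = opts$bin_width_years %||% 5,
                   qc_z = opts$qc_z %||% 6,
                   folds = opts$folds %||% 10,
                   cv = TRUE,
                   importance = isTRUE(opts$importance %||% TRUE),
                   subgroups = isTRUE(opts$subgroups %||% TRUE))

  wr <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(x, path, row.names = FALSE)
    path
  }
  files <- character()
  files <- c(files, wr(res$cohort, "cohort.csv"))
  files <- c(files, wr(res$features, "features77.csv"))
  files <- c(files, wr(res$split, "split.csv"))
  files <- c(files, wr(summarize_split(res$split, res$cohort),
                       "split_summary.csv"))
  files <- c(files, wr(res$predictions, "predictions.csv"))

  for (sx in names(res$models)) {
    p <- file.path(out_dir, paste0("model_", sx, ".json"))
    save_brainage_model(res$models[[sx]], p)
    files <- c(files, p)
  }

  cc <- res$case_control
  cc_tab <- cbind(model = cc$model, cc$result$estimates)
  files <- c(files, wr(cc_tab, "case_control.csv"))

  if (!is.null(res$subgroups)) {
    files <- c(files, wr(res$subgroups$subgroups, "subgroup_table.csv"))
    files <- c(files, wr(res$subgroups$severity, "severity.csv"))
    files <- c(files, wr(res$subgroups$posthoc, "posthoc_contrasts.csv"))
  }
  if (!is.null(res$importance)) {
    files <- c(files, wr(res$importance$structure_coefficients,
                         "structure_coefficients.csv"))
    files <- c(files, wr(res$importance$perturbation, "perturbation.csv"))
    files <- c(files, wr(res$importance$single_modality,
                         "single_modality.csv"))
  }

  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(opts, cfg_json, auto_unbox = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("brainpad")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = opts,
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = cfg$seed,
    stage_seeds = list(simulate = cfg$seed, labels = cfg$seed + 1L,
                       split = cfg$seed + 101L, cv = cfg$seed + 202L,
                       single_modality = cfg$seed + 303L),
    n_participants = nrow(res$cohort),
    n_dropped_qc = res$qc_report$n_dropped,
    case_control = list(model = cc$model, b = cc$effect$b,
                        se = cc$effect$b_se, p = cc$effect$p,
                        d = cc$effect$d, d_se = cc$effect$se,
                        ci = cc$effect$ci),
    cv_metrics = lapply(res$cv, function(m)
      list(mae = m$mae, mae_sd = m$mae_sd, r = m$r, r2 = m$r2, n = m$n)),
    files = basename(files))
  unlink(cfg_json)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
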