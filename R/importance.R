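#' Structure coefficients of a brain-age model
#'
#' Pearson correlations between predicted brain age and each feature,
#' computed in the test samples per group (controls, MDD, pooled). As
#' bivariate correlations they are invariant to affine rescaling of a
#' feature and safe to read as importance summaries alongside a
#' multivariable model whose raw weights are not interpretable one
#' region at a time.
#'
#' @param predictions Output of [predict_brainage()] for the test sample.
#' @param features Feature matrix aligned by `participant_id`.
#' @param group_labels Character vector (`"control"`/`"MDD"`) aligned
#'   with `features` rows, or a cohort data.frame with `participant_id`
#'   and `dx`.
#' @return Data.frame with `feature`, `modality`, `group`, `r`, and a
#'   `flag` column marking zero-variance features.
#' @export
structure_coefficients <- function(predictions, features, group_labels) {
  if (is.data.frame(group_labels) && "dx" %in% names(group_labels)) {
    group_labels <- group_labels$dx[match(features$participant_id,
                                          group_labels$participant_id)]
  }
  stopifnot(length(group_labels) == nrow(features))
  yhat <- predictions$brain_age[match(features$participant_id,
                                      predictions$participant_id)]
  reg <- feature_registry()
  cols <- intersect(reg$feature, names(features))
  groups <- list(controls = group_labels == "control",
                 MDD = group_labels == "MDD",
                 pooled = rep(TRUE, nrow(features)))
  out <- list()
  for (g in names(groups)) {
    idx <- which(groups[[g]] & !is.na(yhat))
    for (j in cols) {
      v <- features[[j]][idx]
      sdv <- if (length(v) >= 2) stats::sd(v) else NA_real_
      flag <- !is.finite(sdv) || sdv == 0
      r <- if (flag) NA_real_ else stats::cor(yhat[idx], v)
      out[[length(out) + 1L]] <- data.frame(
        feature = j, modality = reg$modality[reg$feature == j],
        group = g, r = r, flag = flag, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize structure coefficients by modality
#'
#' @param sc Output of [structure_coefficients()].
#' @param group Which group's rows to summarize (default `"pooled"`).
#' @return Data.frame with mean and SD of r per modality.
#' @export
modality_summary <- function(sc, group = "pooled") {
  d <- sc[sc$group == group & !sc$flag, ]
  agg <- stats::aggregate(r ~ modality, d,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  data.frame(modality = agg$modality, mean_r = agg$r[, "mean"],
             sd_r = agg$r[, "sd"], stringsAsFactors = FALSE)
}

#' Perturb a feature modality and measure the performance change
#'
#' Sets every feature of the chosen modality to its perturbation value in
#' the test matrix and recomputes the MAE with the unchanged model. By
#' default values are zeroed on the standardized scale (equivalent to
#' imputing the training mean on the raw scale); `raw_zero = TRUE` uses
#' literal zeros instead.
#'
#' @param model A `brainage_model`.
#' @param features Test feature matrix.
#' @param ages Chronological ages of the test participants.
#' @param modality One of `"thickness"`, `"surface_area"`,
#'   `"subcortical_volume"`, `"ventricle"`, `"icv"`, or `"none"`.
#' @param raw_zero Use raw zeros instead of training-mean imputation.
#' @return List of class `brainpad_perturbation`: `modality`,
#'   `mae_before`, `mae_after`, `delta_mae` (years).
#' @export
perturb_modality <- function(model, features, ages, modality,
                             raw_zero = FALSE) {
  valid <- c("thickness", "surface_area", "subcortical_volume",
             "ventricle", "icv", "none")
  if (!modality %in% valid)
    stop(sprintf("unknown modality '%s'; valid: %s", modality,
                 paste(valid, collapse = ", ")), call. = FALSE)
  before_pred <- predict_brainage(model, features)
  before_pred$age <- ages
  before_pred$brain_pad <- before_pred$brain_age - ages
  before <- performance_metrics(before_pred)
  pert <- features
  if (modality != "none") {
    reg <- feature_registry()
    cols <- intersect(reg$feature[reg$modality == modality],
                      model$feature_names)
    for (j in cols)
      pert[[j]] <- if (raw_zero) 0 else model$center[[j]]
  }
  after_pred <- predict_brainage(model, pert)
  after_pred$age <- ages
  after_pred$brain_pad <- after_pred$brain_age - ages
  after <- performance_metrics(after_pred)
  out <- list(modality = modality, mae_before = before$mae,
              mae_after = after$mae,
              delta_mae = after$mae - before$mae, raw_zero = raw_zero)
  class(out) <- "brainpad_perturbation"
  out
}

#' @method print brainpad_perturbation
#' @export
print.brainpad_perturbation <- function(x, ...) {
  cat(sprintf("perturb %s: MAE %.2f -> %.2f (delta %+0.2f years)\n",
              x$modality, x$mae_before, x$mae_after, x$delta_mae))
  invisible(x)
}

#' Compare the combined model with single-modality models
#'
#' Fits thickness-only, surface-area-only, subcortical-volume-only
#' (including the lateral ventricle), ICV-only, and combined 77-feature
#' models on identical train/test splits and reports cross-validated and
#' test metrics per variant.
#'
#' @param train_x,train_age Training features (77 columns) and ages.
#' @param test_x,test_age Test features and ages.
#' @param lambda Ridge penalty.
#' @param folds,seed Cross-validation settings.
#' @return Data.frame with one row per variant: feature count, CV MAE/r,
#'   test MAE/r/R2.
#' @export
single_modality_models <- function(train_x, train_age, test_x, test_age,
                                   lambda = 6.5, folds = 10, seed = 1L) {
  reg <- feature_registry()
  sets <- list(
    all77 = reg$feature,
    thickness_only = reg$feature[reg$modality == "thickness"],
    area_only = reg$feature[reg$modality == "surface_area"],
    subcortical_only = reg$feature[reg$modality %in%
                                     c("subcortical_volume", "ventricle")],
    icv_only = "ICV")
  rows <- list()
  for (v in names(sets)) {
    cols <- intersect(sets[[v]], names(train_x))
    trx <- train_x[, c("participant_id", cols), drop = FALSE]
    tex <- test_x[, c("participant_id", cols), drop = FALSE]
    cv <- crossvalidate_brainage(trx, train_age, lambda, folds, seed,
                                 variant = v)
    m <- fit_brainage_model(trx, train_age, lambda, variant = v)
    pred <- predict_brainage(m, tex, age = test_age)
    pm <- performance_metrics(pred)
    rows[[v]] <- data.frame(variant = v, n_features = length(cols),
                            cv_mae = cv$mae, cv_r = cv$r,
                            test_mae = pm$mae, test_r = pm$r,
                            test_r2 = pm$r2, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Plot structure coefficients by modality
#'
#' Strip plot of per-feature structure coefficients, grouped by modality
#' and colored by group. Requires ggplot2.
#'
#' @param sc Output of [structure_coefficients()].
#' @return A ggplot object.
#' @export
plot_structure_coefficients <- function(sc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- sc[sc$group %in% c("controls", "MDD") & !sc$flag, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$modality, y = .data$r,
                                  colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "structure coefficient (Pearson r)") +
    ggplot2::theme_minimal()
}
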