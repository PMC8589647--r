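#' Fit a normative brain-age ridge model
#'
#' Features are z-scored by their training mean and SD, the outcome (age)
#' is centered, and coefficients solve the standardized ridge problem
#' `(Z'Z + n lambda I) b = Z'y` via SVD. The penalty is expressed per
#' training observation (the solver multiplies `lambda` by `n`), so the
#' amount of shrinkage is comparable across training samples of different
#' sizes and across cross-validation folds. With `lambda = 0` the fit
#' equals ordinary least squares. Prediction is affine:
#' `yhat = intercept + sum_f coef_f * (x_f - mean_f) / sd_f`.
#'
#' @param x Feature matrix (data.frame or matrix) without missing values;
#'   a `participant_id` column is ignored.
#' @param age Numeric chronological ages (years).
#' @param lambda Ridge penalty per observation on the standardized scale.
#'   The default is frozen from the same one-time calibration as the
#'   generator noise (see [sim_config()]).
#' @param sex Optional label stored in the model metadata (models are
#'   intended to be fit separately per sex).
#' @param variant Model variant tag, one of `"all77"`,
#'   `"left_right_separate"`, `"thickness_only"`, `"area_only"`,
#'   `"subcortical_only"`, `"icv_only"`.
#' @return Object of class `brainage_model`.
#' @export
fit_brainage_model <- function(x, age, lambda = 6.5, sex = NA_character_,
                               variant = "all77") {
  x <- as_feature_matrix(x)
  stopifnot(length(age) == nrow(x), lambda >= 0)
  if (anyNA(x) || anyNA(age))
    stop("missing values in features or ages", call. = FALSE)
  if (nrow(x) <= ncol(x))
    warning(sprintf("n (%d) <= number of features (%d); fit is ill-posed without regularization",
                    nrow(x), ncol(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  dead <- names(scl)[scl == 0 | !is.finite(scl)]
  if (length(dead))
    stop(sprintf("zero-variance feature(s): %s", paste(dead, collapse = ", ")),
         call. = FALSE)
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  yc <- age - mean(age)
  sv <- svd(z)
  d <- sv$d
  coef <- sv$v %*% ((d / (d^2 + nrow(x) * lambda)) * crossprod(sv$u, yc))
  coef <- drop(coef)
  names(coef) <- colnames(x)
  model <- list(schema_version = "1.0",
                sex = sex, variant = variant,
                feature_names = colnames(x),
                center = ctr, scale = scl,
                coefficients = coef,
                intercept = mean(age),
                lambda = lambda,
                meta = list(n = nrow(x)))
  class(model) <- "brainage_model"
  model
}

#' @method print brainage_model
#' @export
print.brainage_model <- function(x, ...) {
  cat(sprintf("brain-age ridge model [%s]%s: %d features, lambda = %g, n = %d\n",
              x$variant,
              if (is.na(x$sex)) "" else paste0(" (", x$sex, ")"),
              length(x$feature_names), x$lambda, x$meta$n))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[, setdiff(names(x), "participant_id"), drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

#' Predict brain age and brain-PAD
#'
#' Applies a fitted model to new participants; no refitting occurs.
#' Features are aligned to the model's registry by name, so column order
#' is irrelevant; a missing feature is an error. brain-PAD is defined as
#' predicted brain age minus chronological age (years); positive values
#' indicate an older-appearing brain.
#'
#' @param model A `brainage_model`.
#' @param x Feature matrix covering the model's features.
#' @param age Chronological ages (years); optional (`NA` brain-PAD if
#'   absent).
#' @param participant_id Optional ids (taken from `x` if present there).
#' @return Data.frame with `participant_id`, `age`, `brain_age`,
#'   `brain_pad`, `model_variant`, `model_sex`.
#' @export
predict_brainage <- function(model, x, age = NULL, participant_id = NULL) {
  stopifnot(inherits(model, "brainage_model"))
  if (is.data.frame(x) && is.null(participant_id) &&
      "participant_id" %in% names(x))
    participant_id <- x$participant_id
  x <- as_feature_matrix(x)
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop(sprintf("missing feature(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  x <- x[, model$feature_names, drop = FALSE]
  thick <- grepl("_thickavg$", model$feature_names)
  if (any(thick) && any(x[, thick] > 100, na.rm = TRUE))
    warning("thickness values > 100; check feature units (mm expected)")
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  yhat <- drop(z %*% model$coefficients) + model$intercept
  n <- nrow(x)
  if (is.null(participant_id)) participant_id <- as.character(seq_len(n))
  if (is.null(age)) age <- rep(NA_real_, n)
  data.frame(participant_id = participant_id, age = age, brain_age = yhat,
             brain_pad = yhat - age, model_variant = model$variant,
             model_sex = model$sex, stringsAsFactors = FALSE)
}

#' Cross-validate a brain-age model
#'
#' K-fold cross-validation with seeded fold assignment. Out-of-fold
#' predictions are pooled before computing the metrics, matching the
#' convention of reporting a single MAE with the SD of absolute errors.
#' R-squared is reported as the squared Pearson correlation between
#' pooled predictions and age.
#'
#' @inheritParams fit_brainage_model
#' @param folds Number of folds (>= 2, default 10).
#' @param seed Seed for the fold assignment.
#' @return List of class `brainage_cv` with `mae`, `mae_sd`, `r`, `r2`,
#'   `n`, `folds`, `lambda`, and the pooled `predictions`.
#' @export
crossvalidate_brainage <- function(x, age, lambda = 6.5, folds = 10,
                                   seed = 1L, sex = NA_character_,
                                   variant = "all77") {
  x <- as_feature_matrix(x)
  n <- nrow(x)
  stopifnot(folds >= 2, length(age) == n)
  fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  if (min(table(fold)) < 2)
    stop("a fold has fewer than 2 members", call. = FALSE)
  yhat <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    m <- fit_brainage_model(x[tr, , drop = FALSE], age[tr], lambda,
                            sex = sex, variant = variant)
    yhat[!tr] <- predict_brainage(m, x[!tr, , drop = FALSE])$brain_age
  }
  abs_err <- abs(yhat - age)
  r <- stats::cor(yhat, age)
  out <- list(mae = mean(abs_err), mae_sd = stats::sd(abs_err), r = r,
              r2 = r^2, n = n, folds = folds, lambda = lambda,
              predictions = data.frame(age = age, brain_age = yhat))
  class(out) <- "brainage_cv"
  out
}

#' @method print brainage_cv
#' @export
print.brainage_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (n = %d): MAE = %.2f (SD %.2f) years, r = %.3f, R2 = %.3f\n",
              x$folds, x$n, x$mae, x$mae_sd, x$r, x$r2))
  invisible(x)
}

#' Test-sample performance metrics
#'
#' MAE (with SD of absolute errors), Pearson r, and R-squared (squared
#' correlation) of predictions against chronological age.
#'
#' @param predictions Output of [predict_brainage()] (needs `age` and
#'   `brain_age`).
#' @return Named list `mae`, `mae_sd`, `r`, `r2`, `n`.
#' @export
performance_metrics <- function(predictions) {
  e <- abs(predictions$brain_age - predictions$age)
  r <- stats::cor(predictions$brain_age, predictions$age)
  list(mae = mean(e), mae_sd = stats::sd(e), r = r, r2 = r^2,
       n = nrow(predictions))
}

#' Age-range-scaled mean absolute error
#'
#' Divides an MAE by the width of the age range the model covers, giving
#' a dimensionless accuracy that is comparable across studies with
#' different age spans.
#'
#' @param mae MAE in years.
#' @param age_lo,age_hi Age range bounds (years), `age_hi > age_lo`.
#' @return `mae / (age_hi - age_lo)`.
#' @export
#' @examples
#' scaled_mae(4.6, 18, 65)  # ~0.10
scaled_mae <- function(mae, age_lo, age_hi) {
  if (!(age_hi > age_lo)) stop("age range must have positive width",
                               call. = FALSE)
  stopifnot(mae >= 0)
  mae / (age_hi - age_lo)
}

#' Serialize a brain-age model to JSON
#'
#' The model file carries a schema version, the ordered feature registry,
#' per-feature scaler statistics, coefficients, the ridge penalty and
#' training metadata, so a saved model reproduces in-memory predictions
#' exactly on reload.
#'
#' @param model A `brainage_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_brainage_model <- function(model, path) {
  stopifnot(inherits(model, "brainage_model"))
  obj <- unclass(model)
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(obj$scale)
  obj$coefficients <- as.list(obj$coefficients)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname save_brainage_model
#' @export
load_brainage_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || !identical(obj$schema_version, "1.0"))
    stop(sprintf("unsupported model schema version: %s",
                 obj$schema_version %||% "<missing>"), call. = FALSE)
  model <- list(schema_version = obj$schema_version,
                sex = obj$sex %||% NA_character_,
                variant = obj$variant,
                feature_names = obj$feature_names,
                center = unlist(obj$center),
                scale = unlist(obj$scale),
                coefficients = unlist(obj$coefficients),
                intercept = obj$intercept,
                lambda = obj$lambda,
                meta = obj$meta)
  class(model) <- "brainage_model"
  model
}

#' Residualize features on intracranial volume
#'
#' Alternative head-size handling: regress every non-ICV feature on ICV
#' in a reference (training) sample and replace it by the residual; the
#' returned attributes allow applying the same training coefficients to
#' new data.
#'
#' @param features Averaged feature matrix including an `ICV` column.
#' @param fit Optional result of a previous call (its coefficients are
#'   reused; otherwise coefficients are estimated from `features`).
#' @return Feature matrix with ICV regressed out and the `ICV` column
#'   dropped; attribute `"icv_fit"` stores intercepts/slopes.
#' @export
residualize_icv <- function(features, fit = NULL) {
  stopifnot("ICV" %in% names(features))
  icv <- features$ICV
  cols <- setdiff(names(features), c("participant_id", "ICV"))
  if (is.null(fit)) {
    fit <- lapply(cols, function(j) {
      cf <- stats::coef(stats::lm(features[[j]] ~ icv))
      c(intercept = unname(cf[1]), slope = unname(cf[2]))
    })
    names(fit) <- cols
  }
  out <- features
  for (j in cols)
    out[[j]] <- features[[j]] - (fit[[j]][["intercept"]] +
                                   fit[[j]][["slope"]] * icv)
  out$ICV <- NULL
  attr(out, "icv_fit") <- fit
  out
}

#' Estimate the systematic age bias of a brain-age model
#'
#' Regularized age predictors systematically overpredict in the young and
#' underpredict in the old: the regression slope of predicted on
#' chronological age in healthy controls is below 1. This estimates that
#' bias as an intercept/slope pair, by convention from the pooled
#' out-of-fold cross-validation predictions in the training controls (no
#' test data are touched).
#'
#' @param predictions Data.frame with `age` and `brain_age` columns
#'   (e.g. the `predictions` element of [crossvalidate_brainage()]).
#' @return List of class `brainpad_bias` with `alpha` (intercept, years)
#'   and `beta` (slope, dimensionless).
#' @export
estimate_age_bias <- function(predictions) {
  stopifnot(all(c("age", "brain_age") %in% names(predictions)))
  cf <- stats::coef(stats::lm(brain_age ~ age, data = predictions))
  out <- list(alpha = unname(cf[1]), beta = unname(cf[2]))
  class(out) <- "brainpad_bias"
  out
}

#' Correct predictions for the systematic age bias
#'
#' Applies the linear rescaling `(brain_age - alpha) / beta` so that
#' corrected predictions track chronological age with unit slope in
#' controls. This restores the scale of group differences expressed in
#' brain-age years that raw shrunken predictions attenuate. The raw
#' prediction is preserved in `brain_age_raw`; `brain_pad` is recomputed
#' from the corrected prediction.
#'
#' @param predictions Output of [predict_brainage()].
#' @param bias A `brainpad_bias` from [estimate_age_bias()].
#' @return The predictions with `brain_age` corrected, `brain_age_raw`
#'   added, and `brain_pad` updated.
#' @export
apply_age_bias_correction <- function(predictions, bias) {
  stopifnot(inherits(bias, "brainpad_bias"))
  if (!is.finite(bias$beta) || bias$beta <= 0)
    stop("bias slope must be positive and finite", call. = FALSE)
  predictions$brain_age_raw <- predictions$brain_age
  predictions$brain_age <- (predictions$brain_age - bias$alpha) / bias$beta
  predictions$brain_pad <- predictions$brain_age - predictions$age
  predictions
}
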