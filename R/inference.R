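#' Assemble the analysis table for brain-PAD inference
#'
#' Merges pooled predictions with cohort demographics and clinical labels,
#' codes diagnosis and sex as 0/1 indicators, and centers age at the
#' pooled sample mean before squaring (reported age coefficients are on
#' this centered scale). Only participants present in `predictions` are
#' retained, so passing test-side predictions restricts inference to the
#' held-out samples.
#'
#' @param predictions Data.frame from [predict_brainage()] (pooled across
#'   sexes).
#' @param cohort Cohort table.
#' @return Data.frame with `brain_pad`, `dx_mdd`, `male`, `age_c`,
#'   `age_c2`, `site_id`, clinical columns, and attribute `"age_center"`.
#' @export
prepare_pad_data <- function(predictions, cohort) {
  d <- merge(predictions[, c("participant_id", "age", "brain_pad")],
             cohort[, setdiff(names(cohort), "age")],
             by = "participant_id")
  ctr <- mean(d$age)
  d$dx_mdd <- as.numeric(d$dx == "MDD")
  d$male <- as.numeric(d$sex == "male")
  d$age_c <- d$age - ctr
  d$age_c2 <- d$age_c^2
  attr(d, "age_center") <- ctr
  d
}

term_column <- c("dx" = "dx_mdd", "sex" = "male", "age" = "age_c",
                 "age2" = "age_c2", "dx:age" = "dx_mdd:age_c",
                 "dx:sex" = "dx_mdd:male", "age:sex" = "age_c:male",
                 "dx:age:sex" = "dx_mdd:age_c:male")

validate_terms <- function(fixed) {
  if ("age2" %in% fixed && !"age" %in% fixed)
    stop("age2 term requires the age main effect", call. = FALSE)
  key <- function(parts) paste(sort(parts), collapse = ":")
  have <- vapply(strsplit(fixed, ":", fixed = TRUE), key, character(1))
  for (tm in grep(":", fixed, value = TRUE)) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    lower <- as.list(parts)
    if (length(parts) > 2L)
      lower <- c(lower,
                 utils::combn(parts, length(parts) - 1L, simplify = FALSE))
    need <- vapply(lower, key, character(1))
    if (!all(need %in% have))
      stop(sprintf(paste0("interaction %s requires main effects and ",
                          "lower-order interactions %s"), tm,
                   paste(setdiff(need, have), collapse = ", ")),
           call. = FALSE)
  }
  invisible(fixed)
}

#' Fit a site-random-intercept mixed model for brain-PAD
#'
#' Fits `brain_pad ~ fixed terms + (1 | site)` by REML (for reporting)
#' with an ML refit retained for likelihood-ratio tests. Fixed-effect
#' inference uses large-sample Wald z tests (two-sided). With fewer than
#' two sites the model degenerates to ordinary least squares and is
#' flagged `single_site`; a site variance estimated at the boundary is
#' flagged `singular` but not fatal.
#'
#' @param data Output of [prepare_pad_data()] (or any data.frame with the
#'   coded columns).
#' @param fixed Character vector of fixed terms among `"dx"`, `"sex"`,
#'   `"age"`, `"age2"`, `"dx:age"`, `"dx:sex"`, `"age:sex"`,
#'   `"dx:age:sex"`; `age2` requires `age` and interactions require all
#'   their lower-order terms.
#' @param covariates Optional names of additional numeric columns entered
#'   linearly (e.g. a severity score).
#' @param outcome,site Column names of the outcome and grouping factor.
#' @return Object of class `brainpad_mm`: `estimates` (term, estimate,
#'   se, z, p), `sigma_u2`, `sigma_e2`, `logLik_reml`, `logLik_ml`, `n`,
#'   `n1`, `n2`, `n_sites`, `singular`, `single_site`, `dropped`. Terms
#'   the fitter drops for rank deficiency (no support in the data, e.g.
#'   an interaction within a single-sex subgroup) appear in `estimates`
#'   as NA rows and are listed in `dropped`.
#' @export
fit_mixed_model <- function(data, fixed = c("dx", "sex", "age", "age2"),
                            covariates = character(),
                            outcome = "brain_pad", site = "site_id") {
  validate_terms(fixed)
  y <- data[[outcome]]
  stopifnot(!is.null(y))
  # interaction labels are not columns; completeness is on their parts
  cols <- unique(c(outcome, site, covariates,
                   unlist(strsplit(unname(term_column[fixed]), ":"))))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n_sites <- length(unique(d[[site]]))
  n1 <- if ("dx_mdd" %in% names(d)) sum(d$dx_mdd == 0) else NA_integer_
  n2 <- if ("dx_mdd" %in% names(d)) sum(d$dx_mdd == 1) else NA_integer_

  rhs <- c(unname(term_column[fixed]), covariates)
  # terms() may reorder interaction components; key labels by sorted parts
  norm_key <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                                 function(p) paste(sort(p), collapse = ":"),
                                 character(1))
  label_of <- c(stats::setNames(fixed, norm_key(unname(term_column[fixed]))),
                stats::setNames(covariates, covariates),
                "(Intercept)" = "(Intercept)")

  if (stats::var(d[[outcome]]) == 0) {
    est <- data.frame(term = c("(Intercept)", fixed, covariates),
                      estimate = c(d[[outcome]][1], rep(0, length(rhs))),
                      se = NA_real_, z = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    res <- list(estimates = est, sigma_u2 = 0, sigma_e2 = 0,
                logLik_reml = NA_real_, logLik_ml = NA_real_,
                n = nrow(d), n1 = n1, n2 = n2, n_sites = n_sites,
                singular = TRUE, single_site = n_sites < 2)
    class(res) <- "brainpad_mm"
    return(res)
  }

  if (n_sites < 2) {
    f <- stats::reformulate(rhs, response = outcome)
    fit <- stats::lm(f, data = d)
    sm <- summary(fit)$coefficients
    est <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      stringsAsFactors = FALSE)
    sigma_u2 <- 0
    sigma_e2 <- summary(fit)$sigma^2
    ll_reml <- ll_ml <- as.numeric(stats::logLik(fit))
    singular <- TRUE
  } else {
    if (n_sites < 2 || nrow(d) < 4)
      stop("need at least 2 sites with observations", call. = FALSE)
    f <- stats::as.formula(paste(outcome, "~", paste(rhs, collapse = " + "),
                                 "+ (1 |", site, ")"))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = d, REML = TRUE)))
    fit_ml <- suppressMessages(suppressWarnings(lme4::refitML(fit)))
    sm <- as.data.frame(summary(fit)$coefficients)
    est <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"], stringsAsFactors = FALSE)
    vc <- lme4::VarCorr(fit)
    sigma_u2 <- as.numeric(vc[[site]])
    sigma_e2 <- attr(vc, "sc")^2
    ll_reml <- as.numeric(stats::logLik(fit))
    ll_ml <- as.numeric(stats::logLik(fit_ml))
    singular <- lme4::isSingular(fit)
  }
  est$term <- vapply(est$term, function(t) {
    key <- norm_key(t)
    if (!is.na(label_of[key])) unname(label_of[key]) else t
  }, character(1))
  est$z <- est$estimate / est$se
  est$p <- 2 * stats::pnorm(-abs(est$z))
  # terms dropped by the fitter for rank deficiency (e.g. an interaction
  # with no support in a small subgroup) are reported as NA rows
  dropped <- setdiff(c("(Intercept)", fixed, covariates), est$term)
  if (length(dropped))
    est <- rbind(est, data.frame(term = dropped, estimate = NA_real_,
                                 se = NA_real_, z = NA_real_, p = NA_real_,
                                 stringsAsFactors = FALSE))
  rownames(est) <- NULL
  res <- list(estimates = est, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
              logLik_reml = ll_reml, logLik_ml = ll_ml,
              n = nrow(d), n1 = n1, n2 = n2, n_sites = n_sites,
              singular = singular, single_site = n_sites < 2,
              fixed = fixed, covariates = covariates, dropped = dropped)
  class(res) <- "brainpad_mm"
  res
}

#' @method print brainpad_mm
#' @export
print.brainpad_mm <- function(x, ...) {
  cat(sprintf("site-random-intercept model: n = %d (%d sites)%s\n", x$n,
              x$n_sites, if (x$singular) " [singular]" else ""))
  print(x$estimates, digits = 4)
  cat(sprintf("sigma_u2 = %.3f, sigma_e2 = %.3f\n", x$sigma_u2, x$sigma_e2))
  invisible(x)
}

coef_row <- function(res, term) {
  i <- match(term, res$estimates$term)
  if (is.na(i)) stop(sprintf("term %s not in model", term), call. = FALSE)
  res$estimates[i, ]
}

#' Backward elimination over diagnosis-by-age-by-sex interactions
#'
#' Fits the full interaction model (diagnosis, sex, age, age squared,
#' all diagnosis/age/sex interactions); if the three-way interaction is
#' nonsignificant at `alpha` it drops to the two-way model (Dx-by-age and
#' Dx-by-sex); if both two-way diagnosis interactions are nonsignificant
#' it drops to the main-effects model. Interactions that are inestimable
#' in the sample (NA p value) are treated as nonsignificant. Returns the
#' final model.
#'
#' @inheritParams fit_mixed_model
#' @param alpha Per-test retention threshold (default 0.05).
#' @return List with `model` (name), `fixed` (terms) and `result`
#'   (`brainpad_mm` of the final fit).
#' @export
backward_eliminate <- function(data, alpha = 0.05) {
  m1 <- c("dx", "sex", "age", "age2", "dx:age", "dx:sex", "age:sex",
          "dx:age:sex")
  r1 <- fit_mixed_model(data, m1)
  # an interaction that is inestimable in this sample (NA p) cannot be
  # retained, so it is treated as nonsignificant
  p3 <- coef_row(r1, "dx:age:sex")$p
  if (is.finite(p3) && p3 < alpha)
    return(list(model = "model1", fixed = m1, result = r1))
  m2 <- c("dx", "sex", "age", "age2", "dx:age", "dx:sex")
  r2 <- fit_mixed_model(data, m2)
  p2a <- coef_row(r2, "dx:age")$p
  p2b <- coef_row(r2, "dx:sex")$p
  if ((is.finite(p2a) && p2a < alpha) || (is.finite(p2b) && p2b < alpha))
    return(list(model = "model2", fixed = m2, result = r2))
  m3 <- c("dx", "sex", "age", "age2")
  r3 <- fit_mixed_model(data, m3)
  list(model = "model3", fixed = m3, result = r3)
}

#' Likelihood-ratio test of linear vs linear-plus-quadratic age covariates
#'
#' Compares nested ML fits on identical rows: covariate sets
#' (dx, sex, age) vs (dx, sex, age, age squared). The statistic is
#' `2 * (logLik_big - logLik_small)`; the degrees of freedom equal the
#' parameter difference and are reported explicitly.
#'
#' @inheritParams fit_mixed_model
#' @return List `chisq`, `df`, `p`, plus the two ML log-likelihoods.
#' @export
compare_age_terms <- function(data) {
  small <- fit_mixed_model(data, c("dx", "sex", "age"))
  big <- fit_mixed_model(data, c("dx", "sex", "age", "age2"))
  if (small$n != big$n)
    stop("nested fits must use identical rows", call. = FALSE)
  chisq <- max(0, 2 * (big$logLik_ml - small$logLik_ml))
  df <- 1L
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       logLik_small = small$logLik_ml, logLik_big = big$logLik_ml)
}

#' Standard error of Cohen's d (two-sample formula)
#'
#' `SE_d = sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))`.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes.
#' @return Standard error of d.
#' @export
#' @examples
#' round(cohens_d_se(0.14, 2126, 2675), 2)  # 0.03
cohens_d_se <- function(d, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
}

#' Cohen's d from a mixed-model diagnosis effect
#'
#' Standardizes the diagnosis coefficient by the model-implied total
#' residual SD, `d = b / sqrt(sigma_u2 + sigma_e2)`, with the two-sample
#' SE formula and a 95% normal CI.
#'
#' @param result A `brainpad_mm` with a `dx` term and known group sizes.
#' @return List of class `brainpad_effect`: `d`, `se`, `ci` (length-2),
#'   `b`, `b_se`, `p`, `n1`, `n2`.
#' @export
cohens_d_from_model <- function(result) {
  tot <- result$sigma_u2 + result$sigma_e2
  if (!is.finite(tot) || tot <= 0)
    stop("zero residual variance; d undefined", call. = FALSE)
  row <- coef_row(result, "dx")
  d <- row$estimate / sqrt(tot)
  se <- cohens_d_se(d, result$n1, result$n2)
  out <- list(d = d, se = se, ci = c(d - 1.96 * se, d + 1.96 * se),
              b = row$estimate, b_se = row$se, p = row$p,
              n1 = result$n1, n2 = result$n2)
  class(out) <- "brainpad_effect"
  out
}

#' @method print brainpad_effect
#' @export
print.brainpad_effect <- function(x, ...) {
  cat(sprintf("b = %.2f (SE %.2f) years, p = %.2g; d = %.2f (SE %.2f), 95%% CI %.2f-%.2f\n",
              x$b, x$b_se, x$p, x$d, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Case-control brain-PAD analysis
#'
#' Pools predictions across sexes, runs backward elimination over the
#' diagnosis interactions with age, age squared and sex covariates and a
#' scanning-site random intercept, and standardizes the diagnosis effect
#' to Cohen's d. An optional age filter supports sensitivity analyses on
#' restricted age ranges.
#'
#' @param predictions Pooled test-side predictions.
#' @param cohort Cohort table.
#' @param age_range Optional length-2 numeric; participants outside the
#'   closed range are dropped before fitting.
#' @param alpha Retention threshold for the interaction elimination.
#' @return List `model` (selected model name), `result` (`brainpad_mm`),
#'   `effect` (`brainpad_effect`).
#' @export
analyze_case_control <- function(predictions, cohort, age_range = NULL,
                                 alpha = 0.05) {
  d <- prepare_pad_data(predictions, cohort)
  if (!is.null(age_range)) {
    stopifnot(length(age_range) == 2)
    d <- d[d$age >= age_range[1] & d$age <= age_range[2], ]
  }
  if (sum(d$dx_mdd == 1) == 0 || sum(d$dx_mdd == 0) == 0)
    stop("a diagnostic group is empty after filtering", call. = FALSE)
  sel <- backward_eliminate(d, alpha = alpha)
  list(model = sel$model, result = sel$result,
       effect = cohens_d_from_model(sel$result))
}

subgroup_defs <- function() {
  list(all = function(d) d$dx == "MDD",
       first_episode = function(d) !is.na(d$recurrence) & d$recurrence == "first",
       recurrent = function(d) !is.na(d$recurrence) & d$recurrence == "recurrent",
       current = function(d) !is.na(d$remission) & d$remission == "current",
       remitted = function(d) !is.na(d$remission) & d$remission == "remitted",
       ad_free = function(d) !is.na(d$ad_use) & d$ad_use == "free",
       ad_user = function(d) !is.na(d$ad_use) & d$ad_use == "user",
       early_onset = function(d) !is.na(d$onset_category) & d$onset_category == "early",
       middle_onset = function(d) !is.na(d$onset_category) & d$onset_category == "middle",
       late_onset = function(d) !is.na(d$onset_category) & d$onset_category == "late")
}

#' Clinical-subgroup brain-PAD analyses
#'
#' Compares every clinical subgroup of patients (all MDD; first-episode;
#' recurrent; currently depressed; remitted; antidepressant-free and
#' users; early/middle/late onset) against controls with the case-control
#' machinery, fits continuous severity slopes (HDRS-17, BDI-II) within
#' patients, and adjusts the family of 10 subgroup tests plus 2 severity
#' slopes together by Benjamini-Hochberg FDR. Post-hoc patient-only
#' contrasts (first vs recurrent, antidepressant user vs free, remitted
#' vs current, onset categories by likelihood-ratio test) are reported
#' with raw p values.
#'
#' @inheritParams analyze_case_control
#' @param low_n Minimum subgroup size below which a row is flagged.
#' @return List with data.frames `subgroups` (N, b, SE, p, p_fdr, d,
#'   SE_d, CI bounds, low_n flag), `severity`, and `posthoc`.
#' @export
analyze_subgroups <- function(predictions, cohort, alpha = 0.05,
                              low_n = 10L) {
  d <- prepare_pad_data(predictions, cohort)
  defs <- subgroup_defs()
  rows <- list()
  for (nm in names(defs)) {
    in_sub <- defs[[nm]](d) & d$dx == "MDD"
    sub <- d[d$dx == "control" | in_sub, ]
    n_sub <- sum(in_sub)
    if (n_sub == 0) {
      rows[[nm]] <- data.frame(subgroup = nm, n = 0L, b = NA_real_,
                               se_b = NA_real_, p = NA_real_, d = NA_real_,
                               se_d = NA_real_, ci_lo = NA_real_,
                               ci_hi = NA_real_, low_n = TRUE,
                               stringsAsFactors = FALSE)
      next
    }
    sel <- backward_eliminate(sub, alpha = alpha)
    eff <- cohens_d_from_model(sel$result)
    rows[[nm]] <- data.frame(subgroup = nm, n = n_sub, b = eff$b,
                             se_b = eff$b_se, p = eff$p, d = eff$d,
                             se_d = eff$se, ci_lo = eff$ci[1],
                             ci_hi = eff$ci[2], low_n = n_sub < low_n,
                             stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  mdd <- d[d$dx == "MDD", ]
  sev_rows <- lapply(c("hdrs17", "bdi2"), function(v) {
    res <- fit_mixed_model(mdd, fixed = c("sex", "age", "age2"),
                           covariates = v)
    row <- coef_row(res, v)
    data.frame(scale = v, b = row$estimate, se = row$se, p = row$p,
               n = res$n, stringsAsFactors = FALSE)
  })
  severity <- do.call(rbind, sev_rows)

  fam <- c(tab$p, severity$p)
  adj <- rep(NA_real_, length(fam))
  ok <- !is.na(fam)
  adj[ok] <- fdr_adjust(fam[ok])
  tab$p_fdr <- adj[seq_len(nrow(tab))]
  severity$p_fdr <- adj[nrow(tab) + seq_len(nrow(severity))]

  posthoc <- patient_contrasts(mdd)
  list(subgroups = tab, severity = severity, posthoc = posthoc)
}

patient_contrasts <- function(mdd) {
  contrast_bin <- function(col, a, b, label) {
    d <- mdd[!is.na(mdd[[col]]) & mdd[[col]] %in% c(a, b), ]
    if (length(unique(d[[col]])) < 2 || nrow(d) < 20)
      return(data.frame(contrast = label, estimate = NA_real_,
                        df = NA_integer_, p = NA_real_,
                        stringsAsFactors = FALSE))
    d$grp <- as.numeric(d[[col]] == b)
    res <- fit_mixed_model(d, fixed = c("sex", "age", "age2"),
                           covariates = "grp")
    row <- coef_row(res, "grp")
    data.frame(contrast = label, estimate = row$estimate, df = 1L,
               p = row$p, stringsAsFactors = FALSE)
  }
  out <- rbind(
    contrast_bin("recurrence", "first", "recurrent", "first_vs_recurrent"),
    contrast_bin("ad_use", "free", "user", "ad_free_vs_user"),
    contrast_bin("remission", "remitted", "current", "remitted_vs_current"))
  d <- mdd[!is.na(mdd$onset_category), ]
  if (length(unique(d$onset_category)) >= 2 && nrow(d) >= 30) {
    d$on_mid <- as.numeric(d$onset_category == "middle")
    d$on_late <- as.numeric(d$onset_category == "late")
    big <- fit_mixed_model(d, fixed = c("sex", "age", "age2"),
                           covariates = c("on_mid", "on_late"))
    small <- fit_mixed_model(d, fixed = c("sex", "age", "age2"))
    chisq <- max(0, 2 * (big$logLik_ml - small$logLik_ml))
    out <- rbind(out, data.frame(
      contrast = "onset_categories", estimate = chisq, df = 2L,
      p = stats::pchisq(chisq, 2, lower.tail = FALSE),
      stringsAsFactors = FALSE))
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1.
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values in input order.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}
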