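#' Default multi-site composition
#'
#' Twenty-two scanning sites with heterogeneous sizes. Sites s17-s22 enrol
#' females only, so the default cohort is scanned on 16 male and 22 female
#' scanners and contains exactly 1879 male and 2435 female controls and
#' 986 male and 1689 female MDD participants (totals 4314 controls, 2675
#' MDD, 6989 participants).
#'
#' @param scale Positive multiplier applied to all group totals (counts are
#'   re-allocated across sites, so small scales naturally produce sites that
#'   fall below the 10-control inclusion floor).
#' @return A data.frame with one row per site and counts per sex and
#'   diagnosis: `site_id`, `n_control_m`, `n_control_f`, `n_mdd_m`,
#'   `n_mdd_f`.
#' @export
default_site_specs <- function(scale = 1) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  w <- c(2.6, 0.9, 1.5, 0.7, 3.2, 1.1, 0.5, 1.8, 1.3, 0.8, 2.2,
         0.6, 1.0, 1.6, 0.75, 1.4, 0.85, 2.0, 0.55, 1.25, 0.95, 0.65)
  male_sites <- 1:16
  spec <- data.frame(site_id = sprintf("s%02d", 1:22))
  spec$n_control_m <- 0L
  spec$n_control_f <- allocate_counts(round(2435 * scale), w)
  spec$n_mdd_m <- 0L
  spec$n_mdd_f <- allocate_counts(round(1689 * scale), w)
  spec$n_control_m[male_sites] <- allocate_counts(round(1879 * scale),
                                                  w[male_sites])
  spec$n_mdd_m[male_sites] <- allocate_counts(round(986 * scale),
                                              w[male_sites])
  spec
}

#' Default clinical subgroup proportions
#'
#' Proportions of the MDD group falling in each clinical category, with an
#' explicit unknown (NA) share so that expected subgroup counts in a cohort
#' of 2675 MDD participants reproduce the reference composition
#' (903 first-episode / 1648 recurrent; 1786 currently depressed / 298
#' remitted; 939 antidepressant-free / 1717 users; 1035 early / 1218
#' middle-adult / 259 late onset).
#'
#' @return Named list of named probability vectors (each sums to 1).
#' @export
default_subgroup_props <- function() {
  n <- 2675
  list(
    recurrence = c(first = 903 / n, recurrent = 1648 / n,
                   unknown = 1 - (903 + 1648) / n),
    remission = c(current = 1786 / n, remitted = 298 / n,
                  unknown = 1 - (1786 + 298) / n),
    ad_use = c(free = 939 / n, user = 1717 / n,
               unknown = 1 - (939 + 1717) / n),
    onset = c(early = 1035 / n, middle = 1218 / n, late = 259 / n,
              unknown = 1 - (1035 + 1218 + 259) / n)
  )
}

#' Simulation configuration for the synthetic multi-site cohort
#'
#' Bundles every knob of the generator. Defaults emulate the reference
#' mega-analytic cohort: 6989 participants over 22 sites, sex-specific
#' truncated-normal age distributions on 18-75 years, an MDD group shift of
#' `delta_mdd` brain-age years, and calibrated feature noise.
#'
#' @param site_specs Data.frame as returned by [default_site_specs()].
#' @param delta_mdd MDD shift in brain-age years added to the biological
#'   brain age of patients (default 1.08).
#' @param age_dist Named list with truncated-normal parameters per sex and
#'   diagnosis (`mean`, `sd`) on support \[18, 75\].
#' @param archetypes Per-feature mean-function parameters, see
#'   [feature_archetypes()].
#' @param noise_multiplier Global dimensionless multiplier `c` on the
#'   per-feature residual SDs. The default is frozen, together with
#'   `bio_age_sd` and the default ridge penalty, from a one-time grid
#'   calibration (`scripts/calibrate_noise.R`) targeting a female
#'   tenfold-CV MAE near 6.6 years and a bias-corrected within-group
#'   brain-PAD SD near 7.7-8 years.
#' @param bio_age_sd SD (years) of the shared latent biological brain-age
#'   deviation per participant; this is the irreducible within-group
#'   brain-PAD dispersion the generator encodes. Frozen by the same
#'   calibration as `noise_multiplier`.
#' @param subgroup_props See [default_subgroup_props()].
#' @param severity_dist Parameters of the zero-inflated discretized normal
#'   severity scores (HDRS-17 on 0-52, BDI-II on 0-63).
#' @param icv_sd Between-participant SD of intracranial volume (mm3).
#' @param seed Integer seed; (config, seed) fully determines the cohort.
#' @return An object of class `brainpad_sim_config`.
#' @export
sim_config <- function(site_specs = default_site_specs(),
                       delta_mdd = 1.08,
                       age_dist = list(
                         control = list(male = c(mean = 43.1, sd = 15.3),
                                        female = c(mean = 39.4, sd = 15.7)),
                         mdd = list(male = c(mean = 42.8, sd = 13.1),
                                    female = c(mean = 43.2, sd = 14.0))),
                       archetypes = feature_archetypes(),
                       noise_multiplier = 1.0,
                       bio_age_sd = 6.0,
                       subgroup_props = default_subgroup_props(),
                       severity_dist = list(
                         hdrs17 = c(mean = 16, sd = 7, max = 52, p_zero = 0.08),
                         bdi2 = c(mean = 22, sd = 10, max = 63, p_zero = 0.08)),
                       icv_sd = 1.2e5,
                       seed = 1L) {
  cfg <- list(site_specs = site_specs, delta_mdd = delta_mdd,
              age_dist = age_dist, archetypes = archetypes,
              noise_multiplier = noise_multiplier, bio_age_sd = bio_age_sd,
              subgroup_props = subgroup_props, severity_dist = severity_dist,
              icv_sd = icv_sd, seed = as.integer(seed))
  class(cfg) <- "brainpad_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ss <- cfg$site_specs
  need <- c("site_id", "n_control_m", "n_control_f", "n_mdd_m", "n_mdd_f")
  if (!all(need %in% names(ss)))
    stop_config("site_specs must have columns %s", paste(need, collapse = ", "))
  cnt <- as.matrix(ss[, need[-1]])
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop_config("site_specs counts must be nonnegative integers")
  if (sum(cnt) == 0) stop_config("site_specs: all sites are empty")
  if (anyDuplicated(ss$site_id)) stop_config("site_specs: duplicated site_id")
  if (cfg$noise_multiplier <= 0) stop_config("noise_multiplier must be > 0")
  if (cfg$bio_age_sd < 0) stop_config("bio_age_sd must be >= 0")
  for (nm in names(cfg$subgroup_props)) {
    p <- cfg$subgroup_props[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop_config("subgroup_props$%s must be proportions summing to 1", nm)
  }
  invisible(cfg)
}

#' Generate a synthetic multi-site cohort with FreeSurfer-like features
#'
#' Draws demographics per site, a per-participant latent biological brain
#' age `age + delta_mdd * [MDD] + eta` (eta ~ Normal(0, bio_age_sd^2)), and
#' 153 raw morphometric measures whose mean functions follow the feature
#' archetypes: per-feature age slope and curvature evaluated at the latent
#' brain age, sex offset, ICV coupling, Gaussian site offsets (SD
#' `site_tau`) and residual noise (SD `noise_multiplier * sigma`). Left and
#' right hemisphere columns are produced by adding antisymmetric offsets to
#' the averaged signal, so hemisphere averaging recovers the 77-feature
#' matrix exactly.
#'
#' @param config A [sim_config()] object.
#' @return A list with `cohort` (demographics and clinical labels, one row
#'   per participant) and `features` (participant_id plus 153 raw feature
#'   columns including `ICV`).
#' @export
#' @examples
#' sim <- generate_cohort(sim_config(site_specs = default_site_specs(0.02)))
#' table(sim$cohort$dx)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "brainpad_sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    cohort <- draw_demographics(config)
    cohort <- assign_clinical_labels(cohort, config, .reseed = FALSE)
    features <- draw_features(cohort, config)
    list(cohort = cohort, features = features)
  })
}

draw_demographics <- function(config) {
  ss <- config$site_specs
  rows <- list()
  for (i in seq_len(nrow(ss))) {
    for (sex in c("male", "female")) {
      for (dx in c("control", "MDD")) {
        n <- ss[[paste0(if (dx == "control") "n_control_" else "n_mdd_",
                        if (sex == "male") "m" else "f")]][i]
        if (n == 0) next
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = ss$site_id[i], sex = sex, dx = dx, n = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  grid <- do.call(rbind, rows)
  cohort <- grid[rep(seq_len(nrow(grid)), grid$n), c("site_id", "sex", "dx")]
  rownames(cohort) <- NULL
  n <- nrow(cohort)
  cohort$participant_id <- sprintf("p%05d", seq_len(n))
  age <- numeric(n)
  for (dx in c("control", "MDD")) {
    for (sex in c("male", "female")) {
      idx <- cohort$dx == dx & cohort$sex == sex
      if (!any(idx)) next
      par <- config$age_dist[[if (dx == "control") "control" else "mdd"]][[sex]]
      age[idx] <- rtruncnorm(sum(idx), par[["mean"]], par[["sd"]], 18, 75)
    }
  }
  cohort$age <- age
  cohort[, c("participant_id", "site_id", "sex", "age", "dx")]
}

#' Assign clinical subgroup labels and severity scores
#'
#' Labels (recurrence, remission status, antidepressant use, onset
#' category) are drawn independently per clinical dimension from the
#' configured proportions, with an explicit unknown share mapped to `NA`;
#' onset categories infeasible for a participant's age (e.g. late onset
#' at age 30) are renormalized away. Severity scores are drawn
#' independently of the brain features, encoding the null severity
#' association the analysis is designed to detect as absent.
#'
#' @param cohort A cohort data.frame with a populated `dx` column.
#' @param config A [sim_config()] object.
#' @param .reseed Internal; set `FALSE` when already inside a seeded block.
#' @return The cohort with columns `recurrence`, `remission`, `ad_use`,
#'   `onset_category`, `onset_age`, `hdrs17`, `bdi2` added (all `NA` for
#'   controls).
#' @export
assign_clinical_labels <- function(cohort, config, .reseed = TRUE) {
  if (is.null(cohort$dx)) stop_config("cohort$dx must be populated")
  run <- function() {
    n <- nrow(cohort)
    cohort$recurrence <- NA_character_
    cohort$remission <- NA_character_
    cohort$ad_use <- NA_character_
    cohort$onset_category <- NA_character_
    cohort$onset_age <- NA_real_
    cohort$hdrs17 <- NA_real_
    cohort$bdi2 <- NA_real_
    mdd <- which(cohort$dx == "MDD")
    if (length(mdd) == 0) return(cohort)
    pr <- config$subgroup_props
    draw_cat <- function(p, k) {
      lab <- sample(names(p), k, replace = TRUE, prob = p)
      lab[lab == "unknown"] <- NA_character_
      lab
    }
    cohort$recurrence[mdd] <- draw_cat(pr$recurrence, length(mdd))
    cohort$remission[mdd] <- draw_cat(pr$remission, length(mdd))
    cohort$ad_use[mdd] <- draw_cat(pr$ad_use, length(mdd))
    # onset: renormalize over categories feasible given age at scan
    for (i in mdd) {
      a <- cohort$age[i]
      p <- pr$onset
      feas <- c(early = TRUE, middle = a >= 26, late = a >= 56,
                unknown = TRUE)
      p <- p[feas[names(p)]]
      cat <- sample(names(p), 1, prob = p)
      if (cat != "unknown") {
        cohort$onset_category[i] <- cat
        lo <- c(early = 10, middle = 26, late = 56)[[cat]]
        hi <- min(c(early = 25.99, middle = 55.99, late = 75)[[cat]], a)
        cohort$onset_age[i] <- stats::runif(1, lo, max(lo, hi))
      }
    }
    sev <- function(par, k) {
      x <- round(rtruncnorm(k, par[["mean"]], par[["sd"]], 0, par[["max"]]))
      zero <- stats::runif(k) < par[["p_zero"]]
      x[zero] <- 0
      x
    }
    cohort$hdrs17[mdd] <- sev(config$severity_dist$hdrs17, length(mdd))
    cohort$bdi2[mdd] <- sev(config$severity_dist$bdi2, length(mdd))
    cohort
  }
  if (.reseed) with_seed(config$seed + 1L, run()) else run()
}

draw_features <- function(cohort, config) {
  arch <- config$archetypes
  reg_rows <- arch$modality != "icv"
  n <- nrow(cohort)
  male <- as.numeric(cohort$sex == "male")
  bage <- cohort$age + config$delta_mdd * (cohort$dx == "MDD") +
    stats::rnorm(n, 0, config$bio_age_sd)
  t1 <- bage - 40
  t2 <- t1^2

  # ICV: site offset + individual deviation around a sex-specific mean
  icv_row <- arch[arch$modality == "icv", ]
  sites <- sort(unique(cohort$site_id))
  site_idx <- match(cohort$site_id, sites)
  icv_site <- stats::rnorm(length(sites), 0, icv_row$site_tau)
  icv_dev <- icv_site[site_idx] + stats::rnorm(n, 0, config$icv_sd)
  icv <- icv_row$mu + icv_row$sex_off * male + icv_dev

  # site-by-feature offsets for the 76 paired/averaged features
  a76 <- arch[reg_rows, ]
  u <- matrix(stats::rnorm(length(sites) * nrow(a76), 0,
                           rep(a76$site_tau, each = length(sites))),
              nrow = length(sites))

  csig <- config$noise_multiplier * a76$sigma
  x77 <- matrix(0, n, nrow(a76))
  for (f in seq_len(nrow(a76))) {
    x77[, f] <- a76$mu[f] + a76$slope[f] * t1 + a76$quad[f] * t2 +
      a76$sex_off[f] * male + a76$icv_gamma[f] * icv_dev +
      u[site_idx, f] + stats::rnorm(n, 0, csig[f])
  }

  # split to hemispheres with antisymmetric offsets: (L + R) / 2 == x77
  lat <- 0.015 * a76$mu
  out <- data.frame(participant_id = cohort$participant_id,
                    stringsAsFactors = FALSE)
  for (f in seq_len(nrow(a76))) {
    delta <- lat[f] + stats::rnorm(n, 0, 0.4 * csig[f] + 1e-12)
    out[[a76$left[f]]] <- x77[, f] + delta
    out[[a76$right[f]]] <- x77[, f] - delta
  }
  out[["ICV"]] <- icv
  out
}
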