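# Shared fixtures, computed lazily and memoized so expensive simulations
# run once per test session.

.fixtures <- new.env(parent = emptyenv())

# A reduced-scale end-to-end study used by structural tests.
small_study <- function() {
  if (is.null(.fixtures$study)) {
    cfg <- sim_config(site_specs = default_site_specs(0.15), seed = 7L)
    .fixtures$study_config <- cfg
    .fixtures$study <- run_study(cfg, cv = TRUE, importance = TRUE,
                                 subgroups = TRUE)
  }
  .fixtures$study
}

small_study_config <- function() {
  small_study()
  .fixtures$study_config
}

# A reduced-scale raw simulation for generator/bookkeeping tests.
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim_config <- sim_config(site_specs = default_site_specs(0.1),
                                       seed = 11L)
    .fixtures$sim <- generate_cohort(.fixtures$sim_config)
  }
  .fixtures$sim
}

small_sim_config <- function() {
  small_sim()
  .fixtures$sim_config
}

# Paper-scale replicates shared by the acceptance criteria for the group
# effect (b) and its standardized version (d). Seeds fixed a priori.
acceptance_replicates <- function() {
  if (is.null(.fixtures$reps)) {
    .fixtures$reps <- vapply(101:125, function(seed) {
      res <- run_study(sim_config(seed = seed))
      dat <- prepare_pad_data(res$predictions, res$cohort)
      eff <- cohens_d_from_model(
        fit_mixed_model(dat, c("dx", "sex", "age", "age2")))
      c(b = eff$b, d = eff$d)
    }, numeric(2))
  }
  .fixtures$reps
}
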