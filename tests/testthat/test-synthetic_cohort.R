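test_that("default site composition reproduces the reference totals", {
  ss <- default_site_specs()
  expect_equal(nrow(ss), 22L)
  expect_equal(sum(ss$n_control_m), 1879L)
  expect_equal(sum(ss$n_control_f), 2435L)
  expect_equal(sum(ss$n_mdd_m), 986L)
  expect_equal(sum(ss$n_mdd_f), 1689L)
  expect_equal(sum(ss$n_control_m > 0), 16L)
  expect_equal(sum(ss$n_control_f > 0), 22L)
})

test_that("subgroup proportions are probability vectors with the expected counts", {
  pr <- default_subgroup_props()
  for (p in pr) {
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1)
  }
  expect_equal(round(2675 * pr$remission[["remitted"]]), 298)
  expect_equal(round(2675 * pr$recurrence[["first"]]), 903)
  expect_equal(round(2675 * pr$onset[["late"]]), 259)
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config(noise_multiplier = 0), "noise_multiplier")
  expect_error(sim_config(bio_age_sd = -1), "bio_age_sd")
  ss <- default_site_specs()
  ss$n_mdd_f[1] <- -3L
  expect_error(sim_config(site_specs = ss), "nonnegative")
  bad <- default_subgroup_props()
  bad$onset <- bad$onset * 2
  expect_error(sim_config(subgroup_props = bad), "summing to 1")
  empty <- default_site_specs()
  empty[, -1] <- 0L
  expect_error(sim_config(site_specs = empty), "empty")
})

test_that("generate_cohort is deterministic and leaves the caller's RNG alone", {
  cfg <- sim_config(site_specs = default_site_specs(0.05), seed = 42L)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- generate_cohort(sim_config(site_specs = default_site_specs(0.05),
                                   seed = 43L))
  expect_false(identical(s1$features, s3$features))

  set.seed(123)
  r1 <- stats::runif(1)
  set.seed(123)
  invisible(generate_cohort(cfg))
  r2 <- stats::runif(1)
  expect_identical(r1, r2)
})

test_that("cohort dimensions, ids, and age support match the configuration", {
  sim <- small_sim()
  ss <- small_sim_config()$site_specs
  n_expect <- sum(ss$n_control_m + ss$n_control_f + ss$n_mdd_m + ss$n_mdd_f)
  expect_equal(nrow(sim$cohort), n_expect)
  expect_false(anyDuplicated(sim$cohort$participant_id) > 0)
  expect_true(all(sim$cohort$age >= 18 & sim$cohort$age <= 75))
  expect_setequal(unique(sim$cohort$dx), c("control", "MDD"))
  # 76 left/right pairs + ICV = 153 feature columns
  expect_equal(ncol(sim$features) - 1L, 153L)
  expect_identical(sim$features$participant_id, sim$cohort$participant_id)
  # per-site composition honours the spec (spot checks)
  for (i in c(1L, nrow(ss))) {
    in_site <- sim$cohort$site_id == ss$site_id[i]
    expect_equal(sum(in_site & sim$cohort$sex == "male" &
                       sim$cohort$dx == "control"), ss$n_control_m[i])
    expect_equal(sum(in_site & sim$cohort$sex == "female" &
                       sim$cohort$dx == "MDD"), ss$n_mdd_f[i])
  }
})

test_that("clinical labels are NA for controls and feasible for patients", {
  cohort <- small_sim()$cohort
  clin <- c("recurrence", "remission", "ad_use", "onset_category",
            "onset_age", "hdrs17", "bdi2")
  ctl <- cohort[cohort$dx == "control", ]
  for (v in clin) expect_true(all(is.na(ctl[[v]])))

  mdd <- cohort[cohort$dx == "MDD", ]
  expect_true(all(is.na(mdd$recurrence) |
                    mdd$recurrence %in% c("first", "recurrent")))
  expect_true(all(is.na(mdd$remission) |
                    mdd$remission %in% c("current", "remitted")))
  expect_true(all(is.na(mdd$ad_use) | mdd$ad_use %in% c("free", "user")))
  # onset category feasibility given age at scan
  late <- !is.na(mdd$onset_category) & mdd$onset_category == "late"
  expect_true(all(mdd$age[late] >= 56))
  mid <- !is.na(mdd$onset_category) & mdd$onset_category == "middle"
  expect_true(all(mdd$age[mid] >= 26))
  has_onset <- !is.na(mdd$onset_age)
  expect_identical(has_onset, !is.na(mdd$onset_category))
  expect_true(all(mdd$onset_age[has_onset] <= mdd$age[has_onset] + 1e-8))
  # severity scores are integers on the instrument ranges
  expect_true(all(mdd$hdrs17 == round(mdd$hdrs17) &
                    mdd$hdrs17 >= 0 & mdd$hdrs17 <= 52))
  expect_true(all(mdd$bdi2 == round(mdd$bdi2) &
                    mdd$bdi2 >= 0 & mdd$bdi2 <= 63))
})

test_that("standalone label assignment is reproducible and needs dx", {
  cfg <- small_sim_config()
  cohort <- small_sim()$cohort[, c("participant_id", "site_id", "sex",
                                   "age", "dx")]
  l1 <- assign_clinical_labels(cohort, cfg)
  l2 <- assign_clinical_labels(cohort, cfg)
  expect_identical(l1, l2)
  expect_error(assign_clinical_labels(cohort[, 1:4], cfg), "dx")
})

test_that("the MDD shift moves patient features and only patient features", {
  base <- default_site_specs(0.1)
  c0 <- sim_config(site_specs = base, delta_mdd = 0, seed = 99L)
  c5 <- sim_config(site_specs = base, delta_mdd = 5, seed = 99L)
  s0 <- generate_cohort(c0)
  s5 <- generate_cohort(c5)
  expect_identical(s0$cohort$age, s5$cohort$age)
  ctl <- s0$cohort$dx == "control"
  expect_identical(s0$features[ctl, ], s5$features[ctl, ])
  a0 <- average_hemispheres(s0$features)
  a5 <- average_hemispheres(s5$features)
  # older biological brain age => smaller hippocampus, larger ventricles
  expect_true(all(a5$M_hippocampus_vol[!ctl] < a0$M_hippocampus_vol[!ctl]))
  expect_true(all(a5$M_lateralventricle_vol[!ctl] >
                    a0$M_lateralventricle_vol[!ctl]))
})

test_that("feature registry and archetypes are aligned and complete", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 77L)
  expect_equal(as.integer(table(reg$modality)[c("subcortical_volume",
                                                "ventricle", "thickness",
                                                "surface_area", "icv")]),
               c(7L, 1L, 34L, 34L, 1L))
  arch <- feature_archetypes()
  expect_identical(arch$feature, reg$feature)
  expect_true(all(arch$sigma >= 0 & arch$site_tau >= 0))
  # canonical signs: thinning except entorhinal/temporal pole; ventricle grows
  th <- arch[arch$modality == "thickness", ]
  pos <- th$region %in% c("entorhinal", "temporalpole")
  expect_true(all(th$slope[pos] > 0))
  expect_true(all(th$slope[!pos] < 0))
  expect_true(arch$slope[arch$modality == "ventricle"] > 0)
  expect_equal(arch$slope[arch$modality == "icv"], 0)
})
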