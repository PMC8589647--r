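# Directly simulated analysis tables (no imaging pipeline) used to probe
# the inference machinery against known truths.
make_pad_data <- function(n = 1600, n_sites = 8, b_dx = 0, b_age = 0,
                          b_age2 = 0, b_sex = 0, b_dxagesex = 0,
                          sigma = 8, tau = 1, seed = 1) {
  set.seed(seed)
  site <- sample(sprintf("s%02d", seq_len(n_sites)), n, replace = TRUE)
  u <- stats::rnorm(n_sites, 0, tau)
  names(u) <- sprintf("s%02d", seq_len(n_sites))
  age <- stats::runif(n, 18, 75)
  d <- data.frame(
    participant_id = as.character(seq_len(n)), site_id = site,
    dx_mdd = stats::rbinom(n, 1, 0.5), male = stats::rbinom(n, 1, 0.5),
    age_c = age - mean(age), stringsAsFactors = FALSE)
  d$age_c2 <- d$age_c^2
  d$brain_pad <- b_dx * d$dx_mdd + b_age * d$age_c + b_age2 * d$age_c2 +
    b_sex * d$male + b_dxagesex * d$dx_mdd * d$age_c * d$male +
    u[d$site_id] + stats::rnorm(n, 0, sigma)
  d
}

test_that("prepare_pad_data codes indicators and centers age", {
  st <- small_study()
  d <- prepare_pad_data(st$predictions, st$cohort)
  expect_equal(nrow(d), nrow(st$predictions))
  expect_identical(sort(unique(d$dx_mdd)), c(0, 1))
  expect_equal(attr(d, "age_center"), mean(d$age))
  expect_equal(d$age_c, d$age - mean(d$age))
  expect_equal(d$age_c2, d$age_c^2)
  expect_equal(d$male, as.numeric(d$sex == "male"))
})

test_that("single-site fits degrade to the OLS oracle", {
  d <- make_pad_data(n = 120, n_sites = 1, b_dx = 1.2, b_age = -0.2,
                     tau = 0, seed = 2)
  res <- fit_mixed_model(d, c("dx", "sex", "age", "age2"))
  expect_true(res$single_site)
  ols <- summary(stats::lm(brain_pad ~ dx_mdd + male + age_c + age_c2,
                           data = d))$coefficients
  lab <- c("(Intercept)" = "(Intercept)", dx_mdd = "dx", male = "sex",
           age_c = "age", age_c2 = "age2")
  i <- match(unname(lab[rownames(ols)]), res$estimates$term)
  expect_equal(res$estimates$estimate[i], unname(ols[, 1]),
               tolerance = 1e-6)
  expect_equal(res$estimates$se[i], unname(ols[, 2]), tolerance = 1e-6)
  expect_equal(res$sigma_u2, 0)
})

test_that("fixed-term validation rejects incoherent specifications", {
  d <- make_pad_data(n = 100, seed = 3)
  expect_error(fit_mixed_model(d, c("dx", "sex", "age2")), "age2")
  expect_error(fit_mixed_model(d, c("dx", "dx:age")), "main effects")
  expect_error(fit_mixed_model(d, c("dx", "sex", "age", "dx:age:sex")),
               "main effects")
})

test_that("inestimable interactions yield NA rows and a simpler final model", {
  # when every case is female, dx-by-sex terms have no support: the
  # fitter drops them and elimination must fall through, not error
  d <- make_pad_data(n = 600, b_dx = 1, seed = 12)
  d$male[d$dx_mdd == 1] <- 0
  r <- fit_mixed_model(d, c("dx", "sex", "age", "age2", "dx:age",
                            "dx:sex", "age:sex", "dx:age:sex"))
  expect_true(all(c("dx:sex", "dx:age:sex") %in% r$dropped))
  expect_true(is.na(r$estimates$p[r$estimates$term == "dx:age:sex"]))
  expect_true(is.finite(r$estimates$p[r$estimates$term == "dx"]))
  sel <- backward_eliminate(d)
  expect_true(sel$model %in% c("model2", "model3"))
  expect_true(is.finite(cohens_d_from_model(sel$result)$d))
})

test_that("mixed model recovers known effects at multi-site scale", {
  d <- make_pad_data(n = 1600, b_dx = 1.5, b_age = 0.1, b_sex = 0.5,
                     seed = 4)
  res <- fit_mixed_model(d, c("dx", "sex", "age", "age2"))
  expect_false(res$single_site)
  expect_equal(res$n1 + res$n2, nrow(d))
  b <- res$estimates[res$estimates$term == "dx", ]
  expect_lt(abs(b$estimate - 1.5), 4 * b$se)
  a <- res$estimates[res$estimates$term == "age", ]
  expect_lt(abs(a$estimate - 0.1), 4 * a$se)
  # variance components near the generating values
  expect_gt(res$sigma_e2, 49)
  expect_lt(res$sigma_e2, 81)
})

test_that("backward elimination keeps a real three-way interaction and drops absent ones", {
  strong <- make_pad_data(n = 2000, b_dx = 1, b_dxagesex = 0.25, seed = 5)
  sel1 <- backward_eliminate(strong)
  expect_equal(sel1$model, "model1")
  expect_true("dx:age:sex" %in% sel1$fixed)

  none <- make_pad_data(n = 2000, b_dx = 1, seed = 6)
  sel3 <- backward_eliminate(none)
  expect_equal(sel3$model, "model3")
  expect_setequal(sel3$fixed, c("dx", "sex", "age", "age2"))
})

test_that("the age-term likelihood-ratio test detects curvature", {
  quad <- make_pad_data(n = 1500, b_age = 0.1, b_age2 = -0.01, seed = 7)
  lrt <- compare_age_terms(quad)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$chisq, 0)
  expect_lt(lrt$p, 0.01)
  flat <- make_pad_data(n = 1500, b_age = 0.1, seed = 8)
  lrt0 <- compare_age_terms(flat)
  expect_gte(lrt0$chisq, 0)
})

test_that("Cohen's d machinery matches its formulas", {
  expect_equal(cohens_d_se(0.3, 50, 70),
               sqrt((50 + 70) / (50 * 70) + 0.3^2 / (2 * 120)))
  expect_error(cohens_d_se(0.3, 1, 70))
  d <- make_pad_data(n = 1200, b_dx = 1.5, seed = 9)
  res <- fit_mixed_model(d, c("dx", "sex", "age", "age2"))
  eff <- cohens_d_from_model(res)
  b <- res$estimates$estimate[res$estimates$term == "dx"]
  expect_equal(eff$d, b / sqrt(res$sigma_u2 + res$sigma_e2))
  expect_equal(eff$se, cohens_d_se(eff$d, res$n1, res$n2))
  expect_equal(eff$ci, c(eff$d - 1.96 * eff$se, eff$d + 1.96 * eff$se))

  const <- d
  const$brain_pad <- 1
  degenerate <- fit_mixed_model(const, c("dx", "sex", "age", "age2"))
  expect_error(cohens_d_from_model(degenerate), "undefined")
})

test_that("BH adjustment reproduces the hand oracle and its properties", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(10)
  p <- stats::runif(30)^2
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= 1))
  # order equivariance
  o <- sample.int(30)
  expect_equal(fdr_adjust(p[o]), adj[o])
})

test_that("analyze_case_control supports age-restricted sensitivity analyses", {
  st <- small_study()
  full <- st$case_control
  expect_true(is.finite(full$effect$b))
  expect_true(full$model %in% c("model1", "model2", "model3"))
  narrow <- analyze_case_control(st$predictions, st$cohort,
                                 age_range = c(18, 60))
  expect_lt(narrow$result$n, full$result$n)
  ctl_only <- st$cohort[st$cohort$dx == "control", ]
  preds_ctl <- st$predictions[st$predictions$participant_id %in%
                                ctl_only$participant_id, ]
  expect_error(analyze_case_control(preds_ctl, ctl_only, c(18, 75)),
               "empty")
})

test_that("subgroup analyses adjust one 12-test family and report post hocs", {
  st <- small_study()
  sg <- st$subgroups
  expect_equal(nrow(sg$subgroups), 10L)
  expect_equal(sg$subgroups$subgroup[1], "all")
  d <- prepare_pad_data(st$predictions, st$cohort)
  expect_equal(sg$subgroups$n[1], sum(d$dx == "MDD"))
  expect_equal(nrow(sg$severity), 2L)
  expect_setequal(sg$severity$scale, c("hdrs17", "bdi2"))
  fam <- c(sg$subgroups$p, sg$severity$p)
  ok <- !is.na(fam)
  expect_equal(c(sg$subgroups$p_fdr, sg$severity$p_fdr)[ok],
               stats::p.adjust(fam[ok], "BH"))
  expect_true(all(c("first_vs_recurrent", "ad_free_vs_user",
                    "remitted_vs_current") %in% sg$posthoc$contrast))
  if ("onset_categories" %in% sg$posthoc$contrast)
    expect_equal(sg$posthoc$df[sg$posthoc$contrast == "onset_categories"],
                 2L)
  expect_true(all(sg$subgroups$low_n == (sg$subgroups$n < 10)))
})
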