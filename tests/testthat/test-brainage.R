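ridge_toy <- function(n = 20, p = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- drop(x %*% stats::rnorm(p)) + stats::rnorm(n)
  list(x = x, y = y)
}

test_that("ridge solution matches the normal-equations oracle", {
  toy <- ridge_toy()
  lambda <- 2
  m <- fit_brainage_model(toy$x, toy$y, lambda = lambda)
  z <- scale(toy$x)
  yc <- toy$y - mean(toy$y)
  oracle <- solve(crossprod(z) + nrow(toy$x) * lambda * diag(ncol(z)),
                  crossprod(z, yc))
  expect_equal(unname(m$coefficients), unname(drop(oracle)),
               tolerance = 1e-8)
  expect_equal(m$intercept, mean(toy$y))
  expect_equal(unname(m$center), unname(colMeans(toy$x)))
})

test_that("lambda = 0 reproduces ordinary least squares", {
  toy <- ridge_toy()
  m <- fit_brainage_model(toy$x, toy$y, lambda = 0)
  pred <- predict_brainage(m, toy$x, age = toy$y)
  ols <- stats::lm(y ~ x, data = list(y = toy$y, x = toy$x))
  expect_equal(pred$brain_age, unname(stats::fitted(ols)), tolerance = 1e-8)
})

test_that("coefficient norms shrink monotonically in lambda", {
  toy <- ridge_toy()
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l)
    sqrt(sum(fit_brainage_model(toy$x, toy$y, lambda = l)$coefficients^2)),
    numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("predictions are invariant to affine feature rescaling", {
  toy <- ridge_toy()
  m1 <- fit_brainage_model(toy$x, toy$y, lambda = 3)
  x2 <- toy$x
  x2[, 2] <- 100 * x2[, 2] - 7
  m2 <- fit_brainage_model(x2, toy$y, lambda = 3)
  expect_equal(predict_brainage(m1, toy$x)$brain_age,
               predict_brainage(m2, x2)$brain_age, tolerance = 1e-10)
})

test_that("prediction aligns features by name, not position", {
  toy <- ridge_toy()
  m <- fit_brainage_model(toy$x, toy$y, lambda = 1)
  permuted <- toy$x[, rev(colnames(toy$x))]
  expect_equal(predict_brainage(m, permuted)$brain_age,
               predict_brainage(m, toy$x)$brain_age)
  expect_error(predict_brainage(m, toy$x[, -2]), "f2")
})

test_that("degenerate inputs raise informative conditions", {
  toy <- ridge_toy()
  bad <- toy$x
  bad[, 3] <- 1
  expect_error(fit_brainage_model(bad, toy$y), "f3")
  bad2 <- toy$x
  bad2[1, 1] <- NA
  expect_error(fit_brainage_model(bad2, toy$y), "missing values")
  wide <- ridge_toy(n = 10, p = 12)
  expect_warning(fit_brainage_model(wide$x, wide$y), "ill-posed")
})

test_that("cross-validation is seeded, pooled, and guards tiny folds", {
  toy <- ridge_toy(n = 60, p = 5)
  cv1 <- crossvalidate_brainage(toy$x, toy$y, lambda = 1, folds = 5,
                                seed = 3L)
  cv2 <- crossvalidate_brainage(toy$x, toy$y, lambda = 1, folds = 5,
                                seed = 3L)
  expect_identical(cv1, cv2)
  cv3 <- crossvalidate_brainage(toy$x, toy$y, lambda = 1, folds = 5,
                                seed = 4L)
  expect_false(identical(cv1$predictions$brain_age,
                         cv3$predictions$brain_age))
  expect_equal(cv1$n, 60L)
  expect_equal(nrow(cv1$predictions), 60L)
  expect_equal(cv1$mae, mean(abs(cv1$predictions$brain_age - toy$y)))
  expect_equal(cv1$r2, cv1$r^2)
  expect_error(crossvalidate_brainage(toy$x[1:5, ], toy$y[1:5], folds = 3),
               "fewer than 2")
})

test_that("performance metrics and scaled MAE follow their definitions", {
  perfect <- data.frame(age = 1:10, brain_age = 1:10)
  pm <- performance_metrics(perfect)
  expect_equal(pm$mae, 0)
  expect_equal(pm$r, 1)
  expect_equal(scaled_mae(4.6, 18, 65), 4.6 / 47)
  expect_error(scaled_mae(4.6, 65, 18), "positive width")
  expect_error(scaled_mae(-1, 18, 65))
})

test_that("model serialization round-trips exactly and checks the schema", {
  toy <- ridge_toy()
  m <- fit_brainage_model(toy$x, toy$y, lambda = 2, sex = "female")
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_brainage_model(m, path)
  m2 <- load_brainage_model(path)
  expect_equal(predict_brainage(m2, toy$x)$brain_age,
               predict_brainage(m, toy$x)$brain_age, tolerance = 1e-12)
  expect_identical(m2$sex, "female")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$schema_version <- "9.9"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_brainage_model(path), "schema")
})

test_that("age-bias estimation and correction invert a known linear bias", {
  age <- seq(20, 70, length.out = 40)
  preds <- data.frame(participant_id = as.character(seq_along(age)),
                      age = age, brain_age = 5 + 0.8 * age,
                      brain_pad = 5 + 0.8 * age - age)
  bias <- estimate_age_bias(preds)
  expect_equal(bias$alpha, 5, tolerance = 1e-10)
  expect_equal(bias$beta, 0.8, tolerance = 1e-10)
  corr <- apply_age_bias_correction(preds, bias)
  expect_equal(corr$brain_age, age, tolerance = 1e-10)
  expect_equal(corr$brain_pad, rep(0, length(age)), tolerance = 1e-10)
  expect_equal(corr$brain_age_raw, preds$brain_age)

  flat <- data.frame(age = age, brain_age = 50 - 0.2 * age)
  expect_error(apply_age_bias_correction(preds, estimate_age_bias(flat)),
               "positive")
})

test_that("a regularized age model shows the expected attenuation bias", {
  set.seed(8)
  n <- 300
  age <- stats::runif(n, 18, 75)
  slopes <- stats::rnorm(20, 0, 0.5)
  x <- outer(age, slopes) + matrix(stats::rnorm(n * 20, 0, 8), n, 20)
  colnames(x) <- paste0("f", 1:20)
  cv <- crossvalidate_brainage(x, age, lambda = 1, folds = 5, seed = 1L)
  beta <- estimate_age_bias(cv$predictions)$beta
  expect_gt(beta, 0)
  expect_lt(beta, 1)
})

test_that("ICV residualization orthogonalizes and reuses training fits", {
  set.seed(4)
  n <- 120
  icv <- stats::rnorm(n, 1.5e6, 1e5)
  feats <- data.frame(participant_id = as.character(1:n),
                      M_hippocampus_vol = 3000 + 0.001 * icv +
                        stats::rnorm(n, 0, 50),
                      ICV = icv, stringsAsFactors = FALSE)
  out <- residualize_icv(feats)
  expect_false("ICV" %in% names(out))
  expect_lt(abs(stats::cor(out$M_hippocampus_vol, icv)), 1e-10)
  fit <- attr(out, "icv_fit")
  new <- feats[1:10, ]
  out2 <- residualize_icv(new, fit = fit)
  cf <- fit$M_hippocampus_vol
  expect_equal(out2$M_hippocampus_vol,
               new$M_hippocampus_vol -
                 (cf[["intercept"]] + cf[["slope"]] * new$ICV))
})
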