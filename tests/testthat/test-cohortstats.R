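test_that("group comparison: identical groups give t = 0 and the parametric route", {
  set.seed(2)
  x <- rnorm(30)
  res <- compare_groups(x, x)
  expect_equal(res$test_used, "student_t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("normality gate switches to Mann-Whitney only for skewed non-normal groups", {
  set.seed(7)
  heavy <- exp(rnorm(120))^2   # lognormal^2: extreme right skew
  normal <- rnorm(120, mean(heavy), sd(heavy))
  res <- compare_groups(heavy, normal)
  expect_equal(res$test_used, "mann_whitney")
  expect_false(is.na(res$diagnostics$mann_whitney_p))
  # parametric result retained alongside
  expect_false(is.na(res$diagnostics$student_t))

  res2 <- compare_groups(rnorm(60), rnorm(60, 1))
  expect_equal(res2$test_used, "student_t")
})

test_that("type-I error of the gated comparison stays near nominal alpha", {
  set.seed(12)
  reps <- 2000
  rejections <- 0L
  for (r in seq_len(reps)) {
    p <- compare_groups(rnorm(15), rnorm(15))$p
    if (p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("noise-free synthetic cohorts are recovered exactly by OLS", {
  co <- noise_free_cohort(400)
  # a zero-noise fit is exactly collinear with the truth; summary.lm
  # warns about the perfect fit, which is the point of the fixture
  fit <- suppressWarnings(fit_speech_model(co, response = "speech_latent"))
  b <- preset_als()$coef_speech
  est <- setNames(fit$coefficients$estimate, fit$coefficients$predictor)
  expect_close(est[["(Intercept)"]], b[["intercept"]], 1e-8)
  expect_close(est[["age"]], b[["age"]], 1e-8)
  expect_close(est[["normalized_frequency"]], b[["normfreq"]], 1e-8)
  expect_close(est[["spasticity"]], b[["spasticity"]], 1e-8)
  expect_close(est[["fasciculations"]], b[["fasciculations"]], 1e-8)
  expect_close(est[["jaw_jerk"]], b[["jaw_jerk"]], 1e-8)
  expect_close(fit$r_squared, 1, 1e-10)
})

test_that("rank-deficient designs raise a multicollinearity error naming the culprit", {
  co <- simulate_cohort(preset_als(), 60, seed = 4)
  co$jaw_jerk <- co$spasticity  # perfect collinearity
  expect_error(fit_speech_model(co, response = "speech_latent"),
               "collinear.*jaw_jerk")
})

test_that("VIFs match the auxiliary-regression oracle and stay below 2 for independent predictors", {
  co <- simulate_cohort(preset_als(), 1000, seed = 6)
  fit <- fit_speech_model(co, response = "speech_latent")
  for (pred in names(fit$vif)) {
    others <- setdiff(names(fit$vif), pred)
    aux <- lm(stats::as.formula(paste(pred, "~",
                                      paste(others, collapse = "+"))),
              data = co)
    vif_oracle <- 1 / (1 - summary(aux)$r.squared)
    expect_close(fit$vif[[pred]], vif_oracle, 1e-8)
  }
  expect_true(all(fit$vif < 2))
})

test_that("confidence intervals use the Student t quantile at n - k - 1 df", {
  # reconstruction of a published-style bound: estimate 4.68230, SE
  # 1.69174 at df = 31 must give the 95% CI [1.23, 8.13] after rounding
  lo <- 4.68230 - qt(0.975, 31) * 1.69174
  hi <- 4.68230 + qt(0.975, 31) * 1.69174
  expect_equal(round(lo, 2), 1.23)
  expect_equal(round(hi, 2), 8.13)

  # the fitted report reproduces the same construction from its own SEs
  co <- simulate_cohort(preset_als(), 37, seed = 9)
  fit <- fit_speech_model(co, response = "speech_latent")
  expect_equal(fit$df_residual, 37 - 5 - 1)
  with(fit$coefficients, {
    expect_equal(ci_low, estimate - qt(0.975, fit$df_residual) * se,
                 tolerance = 1e-10)
    expect_equal(ci_high, estimate + qt(0.975, fit$df_residual) * se,
                 tolerance = 1e-10)
  })
})

test_that("bootstrap optimism: identity resample gives zero, correction never exceeds apparent", {
  co <- simulate_cohort(preset_als(), 37, seed = 21)
  ident <- bootstrap_optimism(co, response = "speech_latent",
                              indices = list(seq_len(37)))
  expect_equal(ident$optimism, 0)
  expect_equal(ident$corrected_r2, ident$apparent_r2)

  bo <- bootstrap_optimism(co, B = 200, seed = 2, response = "speech_latent")
  expect_gte(bo$optimism, 0)
  expect_lte(bo$corrected_r2, bo$apparent_r2)
  expect_equal(bo$B_effective + bo$B_skipped, 200)
})

test_that("bootstrap optimism vanishes in large samples", {
  co <- simulate_cohort(preset_als(), 3000, seed = 15)
  bo <- bootstrap_optimism(co, B = 30, seed = 3, response = "speech_latent")
  expect_lt(abs(bo$optimism), 0.01)
})

test_that("ordinal sensitivity agrees with OLS for a monotone positive effect", {
  co <- simulate_cohort(preset_als(), 2000, seed = 18)
  ols <- fit_speech_model(co, response = "speech_score")
  ords <- ordinal_sensitivity(co, ols_fit = ols)
  expect_true(ords$converged)
  row <- ords$coefficients[
    ords$coefficients$predictor == "normalized_frequency", ]
  expect_gt(row$estimate, 0)
  expect_true(ords$agreement$sign_agrees)
  expect_true(ords$agreement$significance_agrees)

  co1 <- co
  co1$speech_ord <- 4L
  expect_error(ordinal_sensitivity(co1), "single")
})

test_that("ordinal p-values are near-uniform under a permuted outcome", {
  co <- simulate_cohort(preset_als(), 150, seed = 25)
  set.seed(31)
  pvals <- replicate(200, {
    shuffled <- co
    shuffled$speech_ord <- sample(shuffled$speech_ord)
    fit <- ordinal_sensitivity(shuffled,
                               ols_fit = structure(list(coefficients =
                                 data.frame(predictor = "normalized_frequency",
                                            estimate = 1, p = 1)),
                                 class = "speech_fit"))
    if (!fit$converged) return(NA_real_)
    fit$coefficients$p[fit$coefficients$predictor == "normalized_frequency"]
  })
  pvals <- pvals[!is.na(pvals)]
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.105)
  # gross uniformity: mean of a uniform p-value is 1/2
  expect_close(mean(pvals), 0.5, 0.12)
})
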