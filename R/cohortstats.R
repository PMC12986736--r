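#' Gated two-group comparison
#'
#' Runs the pooled (Student) two-sample t-test as the primary comparison,
#' with Welch's t alongside. Normality of each group is screened with a
#' Lilliefors-type Kolmogorov--Smirnov test (parameters estimated from
#' the data) combined with sample skewness: a group fails the gate when
#' the KS test is significant at `alpha` *and* its absolute skewness
#' exceeds 2. If either group fails, the Mann--Whitney U test is run and
#' reported as the test used, with the parametric result retained in the
#' diagnostics.
#'
#' @param values_a,values_b Numeric vectors (>= 2 values each).
#' @param alpha Gate significance level.
#' @return An object of class `group_test`: `statistic`, `p`,
#'   `test_used` (`"student_t"` or `"mann_whitney"`), and `diagnostics`
#'   (per-group KS p and skewness, Student and Welch results, the
#'   Mann--Whitney result when computed).
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 2 || length(b) < 2)
    stop_param("each group needs at least 2 values")
  student <- t.test(a, b, var.equal = TRUE)
  welch <- t.test(a, b)
  gate_one <- function(x) {
    ks_p <- if (length(x) >= 5 && sd(x) > 0)
      tryCatch(nortest::lillie.test(x)$p.value, error = function(e) NA_real_)
    else NA_real_
    sk <- if (length(x) >= 3 && sd(x) > 0) e1071::skewness(x, type = 2)
    else 0
    list(ks_p = ks_p, skewness = sk,
         fails = isTRUE(ks_p < alpha) && abs(sk) > 2)
  }
  ga <- gate_one(a)
  gb <- gate_one(b)
  nonparam <- ga$fails || gb$fails
  mw <- if (nonparam) wilcox.test(a, b, exact = FALSE) else NULL
  used <- if (nonparam) "mann_whitney" else "student_t"
  structure(list(
    statistic = if (nonparam) unname(mw$statistic)
    else unname(student$statistic),
    p = if (nonparam) mw$p.value else student$p.value,
    test_used = used,
    diagnostics = list(
      group_a = ga[c("ks_p", "skewness")],
      group_b = gb[c("ks_p", "skewness")],
      student_t = unname(student$statistic), student_p = student$p.value,
      welch_t = unname(welch$statistic), welch_p = welch$p.value,
      mann_whitney_U = if (nonparam) unname(mw$statistic) else NA_real_,
      mann_whitney_p = if (nonparam) mw$p.value else NA_real_
    )
  ), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("group comparison (%s): statistic = %.3f, p = %.4g\n",
              x$test_used, x$statistic, x$p))
  cat(sprintf("  Student t = %.3f (p = %.4g); Welch t = %.3f (p = %.4g)\n",
              x$diagnostics$student_t, x$diagnostics$student_p,
              x$diagnostics$welch_t, x$diagnostics$welch_p))
  invisible(x)
}

speech_predictors <- c("age", "normalized_frequency", "spasticity",
                       "fasciculations", "jaw_jerk")

#' Multiple regression of the speech subscore on clinical predictors
#'
#' Ordinary least squares of the speech score on age, normalized tongue
#' movement frequency, and presence of tongue spasticity, tongue
#' fasciculations and an abnormal jaw jerk. Reports per-predictor
#' estimate, SE, t, p and 95% CI (Student t quantile at `n - k - 1`
#' degrees of freedom), multiple R / R^2 / adjusted R^2, variance
#' inflation factors, and residual diagnostics (Shapiro--Wilk normality,
#' Breusch--Pagan homoscedasticity).
#'
#' @param cohort Data frame with the speech outcome and the five
#'   predictor columns (`age`, `normalized_frequency`, `spasticity`,
#'   `fasciculations`, `jaw_jerk`).
#' @param response Name of the outcome column; defaults to
#'   `"speech_score"` (use `"speech_latent"` on synthetic cohorts to
#'   recover the generating model, or an integer item column on real
#'   data).
#' @return An object of class `speech_fit`.
#' @export
fit_speech_model <- function(cohort, response = "speech_score") {
  need <- c(response, speech_predictors)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop_param("cohort lacks columns: %s", paste(missing_cols, collapse = ", "))
  dat <- cohort[, need]
  dat <- dat[complete.cases(dat), ]
  k <- length(speech_predictors)
  if (nrow(dat) <= k + 2)
    stop_param("need more than %d complete rows to fit %d predictors",
               k + 2, k)
  fml <- stats::as.formula(paste(response, "~",
                                 paste(speech_predictors, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (fit$rank < k + 1) {
    bad <- names(which(is.na(coef(fit))))
    stop_param("predictors are collinear (rank deficient): %s",
               paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ci <- confint(fit, level = 0.95)
  tab <- data.frame(
    predictor = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1], se = sm$coefficients[, 2],
    t = sm$coefficients[, 3], p = sm$coefficients[, 4],
    ci_low = ci[, 1], ci_high = ci[, 2], row.names = NULL
  )
  vif <- car::vif(fit)
  res <- stats::residuals(fit)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000)
    shapiro.test(res)$p.value else NA_real_
  bp <- lmtest::bptest(fit)
  structure(list(
    coefficients = tab,
    r = sqrt(sm$r.squared), r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    vif = vif, n = nrow(dat), df_residual = fit$df.residual,
    response = response,
    diagnostics = list(shapiro_p = shapiro_p,
                       breusch_pagan_p = unname(bp$p.value)),
    lm_fit = fit
  ), class = "speech_fit")
}

#' @export
print.speech_fit <- function(x, digits = 4, ...) {
  cat("Model fit statistics\n")
  cat(sprintf("  R = %.3f   R^2 = %.3f   adjusted R^2 = %.3f   (N = %d)\n",
              x$r, x$r_squared, x$adj_r_squared, x$n))
  cat(sprintf("\nRegression coefficients - %s\n", x$response))
  tab <- x$coefficients
  tab$ci <- sprintf("%.2f to %.2f", tab$ci_low, tab$ci_high)
  print(format(tab[, c("predictor", "estimate", "se", "t", "p", "ci")],
               digits = digits), row.names = FALSE)
  cat("\nVIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap optimism correction of the model R-squared
#'
#' Harrell's internal-validation procedure: for each bootstrap resample,
#' the model is refitted and its optimism is the bootstrap-sample R^2
#' minus the R^2 of the bootstrap coefficients evaluated on the original
#' sample; the corrected R^2 is the apparent R^2 minus the mean optimism.
#' Degenerate resamples (constant outcome or collinear design) are
#' skipped and counted.
#'
#' @param cohort Data frame as for [fit_speech_model()].
#' @param B Number of bootstrap iterations (>= 1).
#' @param seed Integer seed; resampling is at the subject level.
#' @param response Outcome column.
#' @param indices Optional list of predefined resample index vectors
#'   (overrides `B` and `seed`); mainly for reproducing a specific
#'   resampling plan.
#' @return An object of class `optimism_boot`: `apparent_r2`, `optimism`
#'   (mean over resamples), `corrected_r2`, `B_effective`, `B_skipped`.
#' @export
bootstrap_optimism <- function(cohort, B = 1000L, seed = 1L,
                               response = "speech_score", indices = NULL) {
  check_number(B, "B", lower = 1)
  apparent_fit <- fit_speech_model(cohort, response = response)
  dat <- apparent_fit$lm_fit$model
  y <- dat[[1]]
  apparent <- apparent_fit$r_squared
  sst <- sum((y - mean(y))^2)
  fml <- stats::formula(apparent_fit$lm_fit)
  set.seed(derive_seed(seed, "optimism"))
  if (is.null(indices))
    indices <- lapply(seq_len(as.integer(B)), function(b)
      sample.int(nrow(dat), replace = TRUE))
  opt <- numeric(0)
  skipped <- 0L
  for (idx in indices) {
    db <- dat[idx, ]
    if (var(db[[1]]) == 0) { skipped <- skipped + 1L; next }
    fb <- tryCatch(lm(fml, data = db), error = function(e) NULL)
    if (is.null(fb) || anyNA(coef(fb))) { skipped <- skipped + 1L; next }
    r2_boot <- summary(fb)$r.squared
    pred_orig <- predict(fb, newdata = dat)
    r2_orig <- 1 - sum((y - pred_orig)^2) / sst
    opt <- c(opt, r2_boot - r2_orig)
  }
  if (length(opt) == 0) stop_param("all %d resamples were degenerate", B)
  optimism <- mean(opt)
  structure(list(apparent_r2 = apparent, optimism = optimism,
                 corrected_r2 = apparent - optimism,
                 B_effective = length(opt), B_skipped = skipped),
            class = "optimism_boot")
}

#' @export
print.optimism_boot <- function(x, ...) {
  cat(sprintf(
    "bootstrap optimism (B = %d, %d skipped): apparent R^2 = %.3f, optimism = %.3f, corrected R^2 = %.3f\n",
    x$B_effective + x$B_skipped, x$B_skipped, x$apparent_r2, x$optimism,
    x$corrected_r2))
  invisible(x)
}

#' Ordinal-logistic sensitivity analysis of the speech model
#'
#' Refits the speech model as a proportional-odds cumulative-logit
#' regression on the ordinal (0--4) speech item and reports coefficient
#' signs and p-values (Wald, normal approximation), flagging whether the
#' normalized-frequency effect agrees in sign and significance with the
#' linear model.
#'
#' @param cohort Data frame with `speech_ord` in `{0..4}` (>= 2 observed
#'   levels) and the predictor columns.
#' @param alpha Significance level used for the agreement flag.
#' @param ols_fit Optional `speech_fit` to compare against; fitted on
#'   `speech_score` if omitted.
#' @return An object of class `ordinal_fit`: coefficient table
#'   (`estimate`, `se`, `z`, `p`, `sign`), `converged`,
#'   `separation_flag`, and `agreement` (sign and significance agreement
#'   of normalized frequency with the OLS fit).
#' @export
ordinal_sensitivity <- function(cohort, alpha = 0.05, ols_fit = NULL) {
  need <- c("speech_ord", speech_predictors)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop_param("cohort lacks columns: %s", paste(missing_cols, collapse = ", "))
  y <- cohort$speech_ord
  if (length(unique(y)) < 2)
    stop_param("speech_ord has a single observed level; ordinal model undefined")
  dat <- cohort[, need]
  dat$speech_ord <- factor(dat$speech_ord, ordered = TRUE)
  fml <- stats::as.formula(paste("speech_ord ~",
                                 paste(speech_predictors, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::polr(fml, data = dat, method = "logistic",
                                Hess = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(coefficients = NULL, converged = FALSE,
                          separation_flag = TRUE,
                          message = conditionMessage(fit),
                          agreement = NA),
                     class = "ordinal_fit"))
  }
  est <- coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(est)]
  separation <- any(abs(est) > 15) || any(!is.finite(se))
  z <- est / se
  tab <- data.frame(predictor = names(est), estimate = unname(est),
                    se = unname(se), z = unname(z),
                    p = unname(2 * pnorm(-abs(z))),
                    sign = sign(unname(est)), row.names = NULL)
  if (is.null(ols_fit))
    ols_fit <- fit_speech_model(cohort, response = "speech_score")
  ols_row <- ols_fit$coefficients[
    ols_fit$coefficients$predictor == "normalized_frequency", ]
  ord_row <- tab[tab$predictor == "normalized_frequency", ]
  agreement <- list(
    sign_agrees = sign(ols_row$estimate) == ord_row$sign,
    significance_agrees = (ols_row$p < alpha) == (ord_row$p < alpha)
  )
  structure(list(coefficients = tab, converged = TRUE,
                 separation_flag = separation, agreement = agreement),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  if (!x$converged) {
    cat("ordinal model did not converge (possible separation):",
        x$message %||% "", "\n")
    return(invisible(x))
  }
  cat("proportional-odds (cumulative logit) sensitivity fit\n")
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  if (isTRUE(x$separation_flag))
    cat("warning: coefficients suggest (quasi-)separation\n")
  cat(sprintf("normalized frequency agrees with OLS: sign %s, significance %s\n",
              x$agreement$sign_agrees, x$agreement$significance_agrees))
  invisible(x)
}
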