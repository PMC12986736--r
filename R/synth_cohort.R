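#' Cohort generator preset
#'
#' Parameters of one simulated participant group: the distribution of the
#' amplitude-normalized tongue-movement frequency (Hz/mm) and of the
#' maximum lateral amplitude (mm), demographics, prevalences of the
#' clinical signs, and (for patient groups) the linear model generating
#' the speech subscore from the covariates. Normalized frequency and
#' amplitude are drawn from Gamma distributions matched to the requested
#' mean and SD, so draws are strictly positive and mildly right-skewed.
#'
#' @param group Group label, e.g. `"ALS"` or `"control"`.
#' @param normfreq_mean,normfreq_sd Mean and SD of normalized frequency
#'   (Hz/mm); mean must be positive.
#' @param amp_mean,amp_sd Mean and SD of maximum amplitude (mm).
#' @param age_mean,age_sd Age distribution (years).
#' @param p_spasticity,p_fasciculations,p_jaw_jerk Prevalences in `[0,1]`.
#' @param p_male Proportion of male participants.
#' @param coef_speech Named coefficients `(intercept, age, normfreq,
#'   spasticity, fasciculations, jaw_jerk)` of the speech-score model, or
#'   `NULL` for a group whose speech item is at ceiling (score 4).
#' @param noise_sd_speech Residual SD of the speech score; `NULL` means
#'   calibrate with [calibrate_speech_noise()] so the population R^2 of
#'   the generating model equals `r2_target`.
#' @param r2_target Population coefficient of determination used by the
#'   noise calibration.
#' @return An object of class `cohort_preset`.
#' @export
cohort_preset <- function(group, normfreq_mean, normfreq_sd,
                          amp_mean = 10, amp_sd = 2,
                          age_mean = 63.9, age_sd = 12.4,
                          p_spasticity = 0, p_fasciculations = 0,
                          p_jaw_jerk = 0, p_male = 0.5,
                          coef_speech = NULL, noise_sd_speech = NULL,
                          r2_target = 0.508) {
  check_number(normfreq_mean, "normfreq_mean", lower = 1e-9)
  check_number(normfreq_sd, "normfreq_sd", lower = 0)
  check_number(amp_mean, "amp_mean", lower = 1e-9)
  check_number(amp_sd, "amp_sd", lower = 0)
  for (p in c("p_spasticity", "p_fasciculations", "p_jaw_jerk", "p_male"))
    check_number(get(p), p, lower = 0, upper = 1)
  if (!is.null(coef_speech)) {
    need <- c("intercept", "age", "normfreq", "spasticity",
              "fasciculations", "jaw_jerk")
    if (!all(need %in% names(coef_speech)))
      stop_param("`coef_speech` must be named with: %s",
                 paste(need, collapse = ", "))
  }
  structure(list(group = group, normfreq_mean = normfreq_mean,
                 normfreq_sd = normfreq_sd, amp_mean = amp_mean,
                 amp_sd = amp_sd, age_mean = age_mean, age_sd = age_sd,
                 p_spasticity = p_spasticity,
                 p_fasciculations = p_fasciculations,
                 p_jaw_jerk = p_jaw_jerk, p_male = p_male,
                 coef_speech = coef_speech,
                 noise_sd_speech = noise_sd_speech,
                 r2_target = r2_target),
            class = "cohort_preset")
}

#' Common within-group SD from a pooled two-sample t statistic
#'
#' Inverts the pooled two-sample t formula,
#' `sigma = (m2 - m1) / (|t| * sqrt(1/n1 + 1/n2))`, to obtain the common
#' within-group SD implied by two group means, a t statistic and the
#' group sizes.
#'
#' @param m1,m2 Group means.
#' @param t_stat Pooled two-sample t statistic (sign ignored).
#' @param n1,n2 Group sizes.
#' @return The implied common SD (positive scalar).
#' @export
derive_common_sd <- function(m1, m2, t_stat, n1, n2) {
  check_number(n1, "n1", lower = 2)
  check_number(n2, "n2", lower = 2)
  if (t_stat == 0) stop_param("`t_stat` must be non-zero")
  abs(m2 - m1) / (abs(t_stat) * sqrt(1 / n1 + 1 / n2))
}

#' Calibrate the speech-score noise SD to a target population R-squared
#'
#' Computes the residual SD `sigma` such that the generating model
#' `speech = X beta + eps`, with covariates distributed as in the preset
#' (independent age, normalized frequency, and Bernoulli signs), has
#' population `R^2 = Var(X beta) / (Var(X beta) + sigma^2)` equal to the
#' preset's target: `sigma^2 = Var(X beta) * (1 - R^2) / R^2`.
#'
#' @param preset A [cohort_preset()] with non-`NULL` `coef_speech`.
#' @param r2 Target R-squared; defaults to the preset's `r2_target`.
#' @return Residual SD (scalar).
#' @export
calibrate_speech_noise <- function(preset, r2 = NULL) {
  stopifnot(inherits(preset, "cohort_preset"))
  if (is.null(preset$coef_speech))
    stop_param("preset has no speech-score model")
  r2 <- r2 %||% preset$r2_target
  check_number(r2, "r2", lower = 1e-9, upper = 1 - 1e-9)
  b <- preset$coef_speech
  var_lp <- b[["age"]]^2 * preset$age_sd^2 +
    b[["normfreq"]]^2 * preset$normfreq_sd^2 +
    b[["spasticity"]]^2 * preset$p_spasticity * (1 - preset$p_spasticity) +
    b[["fasciculations"]]^2 * preset$p_fasciculations *
      (1 - preset$p_fasciculations) +
    b[["jaw_jerk"]]^2 * preset$p_jaw_jerk * (1 - preset$p_jaw_jerk)
  sqrt(var_lp * (1 - r2) / r2)
}

#' Built-in group presets
#'
#' `preset_als()` and `preset_hc()` return the ALS-patient and
#' healthy-control presets used throughout the package: group mean
#' normalized frequencies 0.138 and 0.395 Hz/mm with a common within-group
#' SD obtained from [derive_common_sd()] at `|t| = 9.58` and group sizes
#' 37/20; ALS prevalences of tongue spasticity 0.30, fasciculations 0.38
#' and abnormal jaw jerk 0.19; ages 63.9 +/- 12.4 (ALS) and 61.1 +/- 9.1
#' (controls); and, for the ALS preset, the speech-score regression
#' coefficients with a residual SD calibrated to a population R^2 of
#' 0.508.
#'
#' @return A `cohort_preset`.
#' @export
preset_als <- function() {
  cohort_preset(
    group = "ALS",
    normfreq_mean = 0.138,
    normfreq_sd = derive_common_sd(0.138, 0.395, 9.58, 37, 20),
    amp_mean = 10, amp_sd = 2,
    age_mean = 63.9, age_sd = 12.4,
    p_spasticity = 0.30, p_fasciculations = 0.38, p_jaw_jerk = 0.19,
    p_male = 17 / 37,
    coef_speech = c(intercept = 3.34727, age = -0.0074,
                    normfreq = 4.68230, spasticity = -0.642124,
                    fasciculations = -0.21589, jaw_jerk = -0.29142)
  )
}

#' @rdname preset_als
#' @export
preset_hc <- function() {
  cohort_preset(
    group = "control",
    normfreq_mean = 0.395,
    normfreq_sd = derive_common_sd(0.138, 0.395, 9.58, 37, 20),
    amp_mean = 7.5, amp_sd = 1.5,
    age_mean = 61.1, age_sd = 9.1,
    p_male = 0.5
  )
}

# Gamma draws matched to a mean and SD (positive support); sd = 0 gives
# the constant mean.
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

#' Simulate a clinical cohort
#'
#' Draws per-subject normalized frequency and amplitude from the group
#' preset, binary clinical signs at the preset prevalences, and -- for
#' groups with a speech-score model -- the speech subscore as the linear
#' predictor plus Gaussian noise. Three speech columns are emitted:
#' `speech_latent` (the unbounded continuous score used for model
#' recovery), `speech_score` (the latent score clamped to the 0--4 item
#' range) and `speech_ord` (rounded half-away-from-zero, then clamped to
#' `{0..4}`, as an ALSFRS-R item). Swallowing and salivation items are
#' drawn to complete the bulbar subscore; groups without a speech model
#' are at item ceiling.
#'
#' @param presets A `cohort_preset` or list of them (must be non-empty).
#' @param n_per_group Integer group sizes, recycled over presets.
#' @param seed Integer seed.
#' @return A data frame with one row per subject: demographics,
#'   kinematics, clinical signs, speech/swallowing items, bulbar subscore
#'   and the derived flags `dysarthria` (speech < 4), `dysphagia`
#'   (swallowing < 4), `bulbar_dysfunction` (subscore < 11).
#' @export
simulate_cohort <- function(presets, n_per_group, seed = 1L) {
  if (inherits(presets, "cohort_preset")) presets <- list(presets)
  if (length(presets) == 0) stop_param("`presets` must be non-empty")
  stopifnot(all(vapply(presets, inherits, logical(1), "cohort_preset")))
  n_per_group <- rep_len(as.integer(n_per_group), length(presets))
  set.seed(derive_seed(seed, "cohort"))
  out <- lapply(seq_along(presets), function(gi) {
    pr <- presets[[gi]]
    n <- n_per_group[gi]
    age <- rnorm(n, pr$age_mean, pr$age_sd)
    sex <- ifelse(runif(n) < pr$p_male, "M", "F")
    nf <- rgamma_ms(n, pr$normfreq_mean, pr$normfreq_sd)
    amp <- rgamma_ms(n, pr$amp_mean, pr$amp_sd)
    spast <- rbinom(n, 1, pr$p_spasticity)
    fasc <- rbinom(n, 1, pr$p_fasciculations)
    jaw <- rbinom(n, 1, pr$p_jaw_jerk)
    if (!is.null(pr$coef_speech)) {
      b <- pr$coef_speech
      sdn <- pr$noise_sd_speech %||% calibrate_speech_noise(pr)
      lp <- b[["intercept"]] + b[["age"]] * age + b[["normfreq"]] * nf +
        b[["spasticity"]] * spast + b[["fasciculations"]] * fasc +
        b[["jaw_jerk"]] * jaw
      latent <- lp + rnorm(n, 0, sdn)
      swallow <- clamp(round_half_away(rnorm(n, 3.4, 0.9)), 0, 4)
      saliva <- clamp(round_half_away(rnorm(n, 3.7, 0.6)), 0, 4)
    } else {
      latent <- rep(4, n)
      swallow <- rep(4, n)
      saliva <- rep(4, n)
    }
    speech_score <- clamp(latent, 0, 4)
    speech_ord <- as.integer(clamp(round_half_away(latent), 0, 4))
    bulbar <- speech_ord + as.integer(swallow) + as.integer(saliva)
    data.frame(
      group = pr$group, age = age, sex = sex,
      normalized_frequency = nf, max_amplitude = amp,
      spasticity = spast, fasciculations = fasc, jaw_jerk = jaw,
      speech_latent = latent, speech_score = speech_score,
      speech_ord = speech_ord,
      swallowing_score = as.integer(swallow),
      salivation_score = as.integer(saliva),
      bulbar_subscore = bulbar,
      dysarthria = speech_ord < 4,
      dysphagia = as.integer(swallow) < 4,
      bulbar_dysfunction = bulbar < 11,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  res <- cbind(subject = sprintf("s%04d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Simulate per-subject kinematic ground truth and trajectories
#'
#' For each simulated subject, draws normalized frequency and amplitude
#' from the preset, realizes the cycle frequency on the complete-cycle
#' grid (`round(f * duration) / duration`, so the subject performs a whole
#' number of complete cycles in the scoring window) and synthesizes the
#' tongue-tip displacement series each trial would produce from
#' ground-truth masks: a sampled sinusoid with a random starting phase,
#' quantized to the pixel grid.
#'
#' @param preset A [cohort_preset()].
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param trials Trials per subject.
#' @param fps Frames per second.
#' @param duration Trajectory length in seconds.
#' @param mm_per_px Spatial calibration used for pixel quantization.
#' @param quantize Quantize displacement to whole pixels (as a mask-based
#'   tracker would measure it).
#' @param f_max Physiological ceiling on the implied cycle frequency
#'   (Hz). Subjects whose independent normalized-frequency and amplitude
#'   draws would imply a faster oscillation have their amplitude shrunk
#'   (large excursions cannot be driven arbitrarily fast); the subject's
#'   normalized frequency is unchanged by this adjustment.
#' @return A list of class `kin_cohort`: `subjects` data frame of ground
#'   truth (`normfreq_true`, `amp_true`, `freq_true`, `n_cycles_true`)
#'   and `trajectories`, a list (subjects) of lists (trials) of
#'   `tip_trajectory` objects.
#' @export
simulate_kinematic_cohort <- function(preset, n, seed = 1L, trials = 1L,
                                      fps = 30, duration = 5,
                                      mm_per_px = 0.25, quantize = TRUE,
                                      f_max = 4.5) {
  stopifnot(inherits(preset, "cohort_preset"))
  check_number(n, "n", lower = 1)
  set.seed(derive_seed(seed, paste0("kin-", preset$group)))
  nf <- rgamma_ms(n, preset$normfreq_mean, preset$normfreq_sd)
  amp <- pmax(rgamma_ms(n, preset$amp_mean, preset$amp_sd), 2)
  amp <- pmin(amp, f_max / nf)
  f_raw <- nf * amp
  # every participant completes at least one cycle (the task is always
  # performed; near-zero draws are a tail artifact of the Gamma model)
  n_cyc <- pmax(round_half_away(f_raw * duration), 1)
  freq <- n_cyc / duration
  subjects <- data.frame(
    subject = sprintf("s%04d", seq_len(n)),
    group = preset$group,
    normfreq_true = freq / amp, amp_true = amp,
    freq_true = freq, n_cycles_true = as.integer(n_cyc)
  )
  trajectories <- lapply(seq_len(n), function(i) {
    lapply(seq_len(trials), function(tr) {
      synth_trajectory(freq[i], amp[i], phase = runif(1, 0, 2 * pi),
                       fps = fps, duration = duration,
                       mm_per_px = mm_per_px, quantize = quantize)
    })
  })
  structure(list(subjects = subjects, trajectories = trajectories,
                 preset = preset),
            class = "kin_cohort")
}

#' Analytic tongue-tip trajectory
#'
#' The displacement series `A * sin(2*pi*f*t + phase)` sampled at the
#' frame rate, optionally quantized to the pixel grid to emulate
#' mask-based tip tracking.
#'
#' @param freq Oscillation frequency (Hz).
#' @param amp One-sided amplitude (mm).
#' @param phase Phase in radians.
#' @param fps Frames per second.
#' @param duration Length in seconds.
#' @param mm_per_px Pixel size for quantization.
#' @param quantize Quantize to whole pixels.
#' @return A `tip_trajectory` (see [extract_tip_series()]).
#' @export
synth_trajectory <- function(freq, amp, phase = 0, fps = 30, duration = 5,
                             mm_per_px = 0.25, quantize = TRUE) {
  tt <- seq(0, by = 1 / fps, length.out = as.integer(round(fps * duration)))
  d <- amp * sin(2 * pi * freq * tt + phase)
  if (quantize) d <- round(d / mm_per_px) * mm_per_px
  new_tip_trajectory(time = tt, displacement = d,
                     flag = rep("observed", length(tt)),
                     baseline_x = 0, mm_per_px = mm_per_px, fps = fps)
}
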