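#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run: the scale profile, seed,
#' acquisition and calibration parameters, and the analysis thresholds.
#' Each run logs its fully resolved configuration and seed, and identical
#' configurations with identical seeds produce identical outputs.
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master integer seed.
#' @param profile `"desk"` (reduced scale) or `"full"`.
#' @param n_per_group Subjects per group in synthetic mode.
#' @param trials Trials per subject.
#' @param fps Frames per second.
#' @param mm_per_px Spatial calibration (mm/pixel).
#' @param use_groundtruth_masks Track the tongue on ground-truth masks
#'   (`TRUE`) or on masks predicted by `model_path` (`FALSE`).
#' @param model_path Optional checkpoint for the segmentation stage.
#' @param threshold Mask binarization threshold.
#' @param hysteresis_frac Cycle-detection hysteresis fraction.
#' @param amp_guard Minimum acceptable amplitude (mm).
#' @param max_gap Maximum run of missing frames tolerated by tracking.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("tonguekin_run_"), seed = 1L,
                       profile = c("desk", "full"), n_per_group = 5L,
                       trials = 2L, fps = 30, mm_per_px = 0.25,
                       use_groundtruth_masks = TRUE, model_path = NULL,
                       threshold = 0.5, hysteresis_frac = 0.2,
                       amp_guard = 1, max_gap = 10L) {
  profile <- match.arg(profile)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 profile = profile, n_per_group = as.integer(n_per_group),
                 trials = as.integer(trials), fps = fps,
                 mm_per_px = mm_per_px,
                 use_groundtruth_masks = use_groundtruth_masks,
                 model_path = model_path, threshold = threshold,
                 hysteresis_frac = hysteresis_frac, amp_guard = amp_guard,
                 max_gap = as.integer(max_gap)),
            class = "run_config")
}

log_line <- function(log_path, fmt, ...) {
  cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
}

#' Run the end-to-end synthetic pipeline
#'
#' Synthesizes an ALS-preset and a control-preset group of subjects, each
#' performing the lateralization task `trials` times; renders the
#' ground-truth mask stack of every trial clip; tracks the tongue tip
#' (optionally through a trained segmentation model instead of the true
#' masks); computes the kinematic features per trial and their
#' subject-level trial means; and compares normalized frequency between
#' groups. Trials failing quality control are excluded with a logged
#' reason. All artifacts (trial and subject feature CSVs, statistics
#' report JSON, run log with the resolved configuration) land in
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `features_trials`, `features_subjects`
#'   (data frames), `stats` (list) and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat("", file = log_path)
  log_line(log_path, "tonguekin pipeline run")
  for (nm in setdiff(names(config), "out_dir"))
    log_line(log_path, "  config %s = %s", nm,
             paste(format(config[[nm]]), collapse = ","))
  model <- NULL
  if (!config$use_groundtruth_masks) {
    if (is.null(config$model_path) || !file.exists(config$model_path))
      stop_param("segmentation stage needs an existing model checkpoint")
    model <- load_model(config$model_path)
  }
  presets <- list(preset_als(), preset_hc())
  trial_rows <- list()
  subject_rows <- list()
  for (pr in presets) {
    kin <- simulate_kinematic_cohort(
      pr, config$n_per_group,
      seed = derive_seed(config$seed, paste0("pipe-", pr$group)),
      trials = 1L, fps = config$fps, mm_per_px = config$mm_per_px)
    set.seed(derive_seed(config$seed, paste0("pipe-clips-", pr$group)))
    phases <- matrix(runif(config$n_per_group * config$trials, 0, 2 * pi),
                     config$n_per_group, config$trials)
    clip_seeds <- matrix(sample.int(1e6, config$n_per_group * config$trials),
                         config$n_per_group, config$trials)
    for (i in seq_len(config$n_per_group)) {
      su <- kin$subjects[i, ]
      feats <- list()
      for (tr in seq_len(config$trials)) {
        spec <- clip_spec(fps = config$fps, duration = 5,
                          mm_per_px = config$mm_per_px,
                          freq_true = su$freq_true, amp_true = su$amp_true,
                          phase = phases[i, tr],
                          seed = clip_seeds[i, tr])
        clip <- render_clip(spec, return_frames = !config$use_groundtruth_masks)
        masks <- if (config$use_groundtruth_masks) clip$truth$masks
        else segment_clip(model, clip$frames,
                          threshold = config$threshold)$masks
        ft <- tryCatch({
          traj <- extract_tip_series(masks, fps = config$fps,
                                     mm_per_px = config$mm_per_px,
                                     max_gap = config$max_gap)
          compute_features(traj, amp_guard = config$amp_guard,
                           hysteresis_frac = config$hysteresis_frac)
        }, error = function(e) e)
        if (inherits(ft, "error")) {
          log_line(log_path, "QC exclusion: %s %s trial %d: %s",
                   pr$group, su$subject, tr, conditionMessage(ft))
          next
        }
        feats[[length(feats) + 1]] <- ft
        trial_rows[[length(trial_rows) + 1]] <- data.frame(
          subject = paste0(pr$group, "_", su$subject), group = pr$group,
          trial = tr, n_cycles = ft$n_cycles, frequency_hz = ft$frequency,
          max_amplitude_mm = ft$max_amplitude,
          normalized_frequency_hz_per_mm = ft$normalized_frequency)
      }
      if (length(feats) == 0) {
        log_line(log_path, "QC exclusion: %s %s: no scorable trials",
                 pr$group, su$subject)
        next
      }
      avg <- if (length(feats) >= 2) average_trials(feats[[1]], feats[[2]])
      else suppressWarnings(average_trials(feats[[1]]))
      subject_rows[[length(subject_rows) + 1]] <- data.frame(
        subject = paste0(pr$group, "_", su$subject), group = pr$group,
        n_trials = length(feats), n_cycles = avg$n_cycles,
        frequency_hz = avg$frequency,
        max_amplitude_mm = avg$max_amplitude,
        normalized_frequency_hz_per_mm = avg$normalized_frequency)
    }
  }
  features_trials <- do.call(rbind, trial_rows)
  features_subjects <- do.call(rbind, subject_rows)
  trials_path <- file.path(config$out_dir, "features_trials.csv")
  subjects_path <- file.path(config$out_dir, "features_subjects.csv")
  write.csv(features_trials, trials_path, row.names = FALSE)
  write.csv(features_subjects, subjects_path, row.names = FALSE)
  groups <- split(features_subjects$normalized_frequency_hz_per_mm,
                  features_subjects$group)
  stats <- list(group_means = lapply(groups, mean),
                group_sds = lapply(groups, sd))
  if (all(lengths(groups) >= 2)) {
    gt <- compare_groups(groups[["ALS"]], groups[["control"]])
    stats$comparison <- list(test_used = gt$test_used,
                             statistic = gt$statistic, p = gt$p)
  }
  stats_path <- file.path(config$out_dir, "stats_report.json")
  jsonlite::write_json(stats, stats_path, auto_unbox = TRUE, digits = NA)
  log_line(log_path, "wrote %s (%d trial rows), %s (%d subject rows), %s",
           trials_path, nrow(features_trials), subjects_path,
           nrow(features_subjects), stats_path)
  invisible(list(features_trials = features_trials,
                 features_subjects = features_subjects, stats = stats,
                 paths = list(trials = trials_path, subjects = subjects_path,
                              stats = stats_path, log = log_path)))
}
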