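test_that("end-to-end synthetic run produces the expected artifact shapes", {
  out <- tempfile("run_")
  cfg <- run_config(out_dir = out, seed = 7, n_per_group = 5, trials = 2)
  res <- run_pipeline(cfg)
  # 2 groups x 5 subjects x 2 trials
  expect_equal(nrow(res$features_trials), 20)
  expect_equal(nrow(res$features_subjects), 10)
  expect_true(file.exists(res$paths$trials))
  expect_true(file.exists(res$paths$subjects))
  expect_true(file.exists(res$paths$stats))
  # run log carries the resolved configuration and seed
  log_txt <- readLines(res$paths$log)
  expect_true(any(grepl("seed = 7", log_txt)))
  expect_true(any(grepl("mm_per_px", log_txt)))
  # subject-level rows are trial means
  tr <- res$features_trials
  su <- res$features_subjects
  for (s in su$subject) {
    expect_close(su$normalized_frequency_hz_per_mm[su$subject == s],
                 mean(tr$normalized_frequency_hz_per_mm[tr$subject == s]),
                 1e-12)
  }
  # the groups separate in the expected direction
  expect_lt(res$stats$group_means$ALS, res$stats$group_means$control)
  unlink(out, recursive = TRUE)
})

test_that("identical config and seed reproduce identical outputs", {
  runs <- lapply(1:2, function(k) {
    out <- tempfile(sprintf("rep%d_", k))
    res <- run_pipeline(run_config(out_dir = out, seed = 3,
                                   n_per_group = 2, trials = 2))
    csv <- read.csv(res$paths$trials)
    unlink(out, recursive = TRUE)
    csv
  })
  expect_identical(runs[[1]], runs[[2]])
})

test_that("segmentation stage demands a checkpoint", {
  cfg <- run_config(out_dir = tempfile(), use_groundtruth_masks = FALSE)
  expect_error(run_pipeline(cfg), "checkpoint")
})

test_that("mask and frame PNG round-trips preserve content", {
  cl <- render_clip(tiny_clip_spec(seed = 41))
  d1 <- tempfile("masks_")
  write_masks(cl$truth$masks[, , 1:5], d1)
  back <- read_masks(d1)
  expect_identical(back, cl$truth$masks[, , 1:5])
  d2 <- tempfile("frames_")
  write_frames(cl$frames[, , , 1:3, drop = FALSE], d2)
  fr <- read_frames(d2)
  expect_equal(dim(fr), c(72, 96, 3, 3))
  expect_lt(max(abs(fr - cl$frames[, , , 1:3])), 1 / 255)  # 8-bit quantized
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("dataset manifests and YAML configs round-trip", {
  ds <- generate_segmentation_dataset(5, size = 24, seed = 2)
  dir <- tempfile("ds_")
  write_manifest(ds, dir)
  back <- read_manifest(dir)
  expect_length(back$images, 5)
  expect_identical(back$participant, ds$participant)
  expect_identical(lapply(back$masks, function(m) m > 0.5),
                   lapply(ds$masks, function(m) m > 0.5))
  yml <- tempfile(fileext = ".yaml")
  save_config_yaml(tiny_clip_spec(seed = 3), yml)
  cfg <- load_config_yaml(yml)
  expect_equal(cfg$freq_true, 2)
  expect_equal(cfg$mm_per_px, 0.5)
  unlink(dir, recursive = TRUE); unlink(yml)
})

test_that("command-line interface runs the cohort and stats subcommands", {
  cli <- system.file("cli", "tonguekin.R", package = "tonguekin")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  out_csv <- tempfile(fileext = ".csv")
  status <- system2(rscript, c(cli, "synth-cohort", "--n", "25",
                               "--seed", "5", "--out", out_csv),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_csv))
  co <- read.csv(out_csv)
  expect_equal(nrow(co), 50)  # 25 per group
  out_json <- tempfile(fileext = ".json")
  system2(rscript, c(cli, "stats", "--cohort", out_csv,
                     "--out", out_json), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_json))
  rep <- jsonlite::read_json(out_json)
  expect_true(!is.null(rep$regression$coefficients))
  # unknown subcommand: non-zero exit
  bad <- suppressWarnings(
    system2(rscript, c(cli, "frobnicate"), stdout = FALSE, stderr = FALSE))
  expect_true(bad != 0)
  unlink(c(out_csv, out_json))
})
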