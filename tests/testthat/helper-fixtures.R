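# Shared fixtures, all generated in code.

# cross-file scratch space (e.g. reusing the heavyweight CV run for the
# leakage audit)
.fixture_cache <- new.env(parent = emptyenv())

# small, fast clip spec for rendering tests
tiny_clip_spec <- function(...) {
  defaults <- list(fps = 30, duration = 5, width = 96L, height = 72L,
                   mm_per_px = 0.5, freq_true = 2, amp_true = 8,
                   tongue_axes = c(6, 4.5))
  do.call(clip_spec, utils::modifyList(defaults, list(...)))
}

# a static stack of identical single-column masks (zero-width tongue):
# the degenerate case where tip and centroid coincide
static_column_masks <- function(n_frames = 20, H = 20, W = 30, col = 15) {
  m <- matrix(0, H, W)
  m[8:12, col] <- 1
  array(rep(m, n_frames), c(H, W, n_frames))
}

# tiny segmentation dataset + config for structural tests
tiny_seg_setup <- function(n = 12, size = 32, n_folds = 2, epochs = 1,
                           seed = 7) {
  list(dataset = generate_segmentation_dataset(n, size = size,
                                               images_per_participant = 3,
                                               seed = seed),
       config = seg_train_config(input_size = size, depth = 2, width = 1 / 8,
                                 epochs = epochs, batch_size = 8,
                                 n_folds = n_folds, seed = seed))
}

# cohort with zero speech noise: exact linear recovery fixture
noise_free_cohort <- function(n = 400, seed = 11) {
  pr <- preset_als()
  pr$noise_sd_speech <- 0
  simulate_cohort(pr, n, seed = seed)
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
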