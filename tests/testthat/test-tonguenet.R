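test_that("Dice and IoU follow their definitions and conventions", {
  a <- matrix(0, 6, 6); a[2:4, 2:4] <- 1
  expect_equal(dice_iou(a, a), list(dice = 1, iou = 1))
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(dice_iou(a, b), list(dice = 0, iou = 0))
  # |A| = |B| = 4, overlap 2
  p <- matrix(0, 4, 4); p[1, 1:4] <- 1
  g <- matrix(0, 4, 4); g[1, 3:4] <- 1; g[2, 1:2] <- 1
  m <- dice_iou(p, g)
  expect_equal(m$dice, 0.5)
  expect_equal(m$iou, 1 / 3)
  # empty-mask conventions
  z <- matrix(0, 4, 4)
  expect_equal(dice_iou(z, z), list(dice = 1, iou = 1))
  expect_equal(dice_iou(z, g), list(dice = 0, iou = 0))
  expect_error(dice_iou(matrix(0, 3, 3), z), "shape")
})

test_that("dice = 2*iou/(1+iou) holds to 1e-12 on random mask pairs", {
  set.seed(42)
  for (r in 1:25) {
    p <- matrix(rbinom(100, 1, 0.4), 10)
    g <- matrix(rbinom(100, 1, 0.4), 10)
    m <- dice_iou(p, g)
    if (m$iou > 0)
      expect_lt(abs(m$dice - 2 * m$iou / (1 + m$iou)), 1e-12)
  }
})

test_that("combined BCE + soft-Dice loss matches hand computations", {
  g <- matrix(c(1, 1, 0, 0), 2)
  # near-perfect prediction: loss close to zero
  perfect <- matrix(c(0.999, 0.999, 0.001, 0.001), 2)
  expect_lt(loss_bce_softdice(perfect, g), 0.01)
  # uniform 0.5 on a 4-pixel image with 2 positives: soft-Dice term is
  # 1 - (2*1 + eps) / (2 + 2 + eps) with eps = 1
  u <- matrix(0.5, 2, 2)
  expect_equal(loss_bce_softdice(u, g, w_bce = 0, w_dice = 1),
               1 - 3 / 5)
  # directional sanity: moving a wrong pixel toward its label lowers loss
  wrong <- matrix(c(0.9, 0.9, 0.8, 0.1), 2)
  better <- wrong; better[1, 2] <- 0.4  # pixel (1,2) has label 0
  expect_lt(loss_bce_softdice(better, g), loss_bce_softdice(wrong, g))
  expect_error(loss_bce_softdice(matrix(0.5, 3, 3), g), "shape")
})

test_that("logit-space training loss agrees with the probability-space loss", {
  set.seed(3)
  z <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  g <- array(rbinom(16 * 16 * 2, 1, 0.5), c(16, 16, 1, 2))
  lg <- tonguekin:::loss_grad_from_logits(z, g, w_bce = 1, w_dice = 1)
  ref <- loss_bce_softdice(1 / (1 + exp(-z)), g)
  expect_close(lg$loss, ref, 1e-8)
})

test_that("preprocessing resizes to the working resolution and normalizes to [0,1]", {
  set.seed(5)
  img <- array(runif(108 * 192 * 3, 0, 255), c(108, 192, 3))
  out <- preprocess_image(img, size = 64)
  expect_equal(dim(out), c(64, 64, 3))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  # already at size in [0,1]: unchanged
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_identical(preprocess_image(x, size = 64), x)
  # constant image stays constant
  k <- array(0.3, c(50, 80, 3))
  expect_true(all(abs(preprocess_image(k, size = 64) - 0.3) < 1e-12))
  expect_error(preprocess_image(numeric(0)), "non-empty")

  m <- matrix(rbinom(70 * 90, 1, 0.3), 70, 90)
  pm <- preprocess_mask(m, size = 64)
  expect_equal(dim(pm), c(64, 64))
  expect_true(all(pm %in% c(0, 1)))
})

test_that("model construction: nested topology size, width scaling, seeded init", {
  cfg_half <- seg_train_config(input_size = 32, depth = 2, width = 1 / 2,
                               seed = 1)
  cfg_quarter <- seg_train_config(input_size = 32, depth = 2, width = 1 / 4,
                                  seed = 1)
  m_half <- build_model(cfg_half)
  m_quarter <- build_model(cfg_quarter)
  expect_lt(n_params(m_quarter), n_params(m_half))
  # every nested node of the L = 2 topology exists
  for (key in c("x0_0", "x1_0", "x2_0", "x0_1", "x1_1", "x0_2"))
    expect_true(paste0(key, ".w1") %in% names(m_half$params))

  # forward contract: probability map with the input's spatial shape
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p <- unetpp_predict(m_quarter, x)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p > 0 & p < 1))

  # seeded determinism of initial weights
  m_again <- build_model(cfg_half)
  expect_identical(m_half$params, m_again$params)
  cfg_other <- seg_train_config(input_size = 32, depth = 2, width = 1 / 2,
                                seed = 2)
  expect_false(identical(build_model(cfg_other)$params, m_half$params))

  expect_error(seg_train_config(input_size = 100), "multiple of 16")
  expect_error(seg_train_config(input_size = 48, depth = 5), "2\\^depth")
})

test_that("grouped cross-validation is exhaustive, leakage-free, and label-blind", {
  ts <- tiny_seg_setup(n = 12, n_folds = 3)
  cv <- train_crossval(ts$dataset, ts$config)
  # every image validated exactly once
  expect_false(anyNA(cv$per_image$dice))
  expect_equal(sort(unique(cv$per_image$fold)), 1:3)
  # participants never straddle folds
  tab <- table(cv$per_image$participant, cv$per_image$fold)
  expect_true(all(rowSums(tab > 0) == 1))
  # too few participants for the requested folds
  cfg10 <- seg_train_config(input_size = 32, depth = 2, width = 1 / 8,
                            epochs = 1, n_folds = 10)
  expect_error(train_crossval(ts$dataset, cfg10), "folds")
  # diagnostic labels are rejected at the interface
  poisoned <- ts$dataset
  poisoned$group <- rep("ALS", 12)
  expect_error(train_crossval(poisoned, ts$config), "diagnostic")
})

test_that("training decreases the running loss over the first five epochs", {
  ds <- generate_segmentation_dataset(8, size = 32,
                                      images_per_participant = 2, seed = 3)
  cfg <- seg_train_config(input_size = 32, depth = 2, width = 1 / 8,
                          epochs = 5, batch_size = 8, learning_rate = 1e-3,
                          seed = 3)
  m <- build_model(cfg)
  m <- train_unetpp(m, lapply(ds$images, preprocess_image, size = 32),
                    lapply(ds$masks, preprocess_mask, size = 32))
  expect_length(m$history, 5)
  expect_true(all(diff(m$history) < 0))
})

test_that("clip segmentation enforces training state and returns one mask per frame", {
  cfg <- seg_train_config(input_size = 32, depth = 2, width = 1 / 8,
                          epochs = 1, seed = 1)
  m <- build_model(cfg)
  cl <- render_clip(tiny_clip_spec(seed = 17))
  expect_error(segment_clip(m, cl$frames), "untrained")

  m$trained <- TRUE  # structural contract only; weights are random
  res <- segment_clip(m, cl$frames[, , , 1:6, drop = FALSE])
  expect_equal(dim(res$masks), c(72, 96, 6))
  expect_length(res$empty, 6)
})

test_that("model checkpoints round-trip through a single file", {
  ts <- tiny_seg_setup()
  m <- build_model(ts$config)
  m$trained <- TRUE
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_identical(m2$config$input_size, ts$config$input_size)
  unlink(path)
})
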