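#' Participant-grouped cross-validated training and evaluation
#'
#' Partitions participants (never single images) into `n_folds` mutually
#' exclusive folds, trains a fresh U-Net++ on the out-of-fold images each
#' time, and evaluates Dice and IoU on the held-out fold, so that every
#' image is validated exactly once and no participant contributes to both
#' training and validation of the same fold. Fold membership is formed by
#' shuffling the participant keys under the run seed and dealing them
#' round-robin. The absence of train/validation participant overlap is
#' asserted on every run. Training consumes images, masks and participant
#' keys only; diagnostic labels have no representation in this interface,
#' and a dataset carrying a `group` field is rejected outright.
#'
#' @param dataset A `seg_dataset` (images, masks, participant keys) from
#'   [generate_segmentation_dataset()] or [read_manifest()].
#' @param config A [seg_train_config()].
#' @param verbose Print per-fold progress.
#' @return An object of class `seg_cv`: `per_image` (fold, participant,
#'   dice, iou per image), `per_fold` (fold means and SDs), `mean_dice`,
#'   `sd_dice`, `mean_iou`, `sd_iou`, `fold_assignment` (participant ->
#'   fold log) and the config.
#' @export
train_crossval <- function(dataset, config, verbose = FALSE) {
  stopifnot(inherits(config, "seg_train_config"))
  if (!is.null(dataset$group) || !is.null(dataset$diagnosis))
    stop_param("segmentation training must not receive diagnostic labels")
  n <- length(dataset$images)
  if (n == 0) stop_param("dataset is empty")
  keys <- dataset$participant
  uk <- unique(keys)
  if (length(uk) < config$n_folds)
    stop_param("%d distinct participants cannot fill %d folds",
               length(uk), config$n_folds)
  set.seed(derive_seed(config$seed, "folds"))
  shuffled <- sample(uk)
  fold_of_key <- setNames(rep_len(seq_len(config$n_folds), length(shuffled)),
                          shuffled)
  fold <- unname(fold_of_key[keys])
  size <- config$input_size
  prep_x <- lapply(dataset$images, preprocess_image, size = size)
  prep_y <- lapply(dataset$masks, preprocess_mask, size = size)
  per_image <- data.frame(index = seq_len(n), participant = keys,
                          fold = fold, dice = NA_real_, iou = NA_real_)
  thresholds <- rep(config$threshold, config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- which(fold != f)
    va <- which(fold == f)
    stopifnot(length(intersect(keys[tr], keys[va])) == 0)  # leakage guard
    if (length(va) == 0) next
    if (verbose)
      message(sprintf("fold %d/%d: %d train, %d validation images",
                      f, config$n_folds, length(tr), length(va)))
    model <- build_model(config, in_channels = dim(prep_x[[1]])[3])
    model <- train_unetpp(model, prep_x[tr], prep_y[tr], verbose = verbose)
    thr <- config$threshold
    if (isTRUE(config$calibrate_threshold)) {
      # operating-point calibration on training images only
      probs <- lapply(tr, function(i) unetpp_predict(model, prep_x[[i]]))
      grid <- seq(0.05, 0.95, by = 0.025)
      mean_dice <- vapply(grid, function(th)
        mean(mapply(function(p, i) dice_iou(p >= th, prep_y[[i]])$dice,
                    probs, tr)), numeric(1))
      thr <- grid[which.max(mean_dice)]
      if (verbose) message(sprintf("  calibrated threshold: %.3f", thr))
    }
    thresholds[f] <- thr
    for (i in va) {
      prob <- unetpp_predict(model, prep_x[[i]])
      m <- dice_iou(prob >= thr, prep_y[[i]])
      per_image$dice[i] <- m$dice
      per_image$iou[i] <- m$iou
    }
  }
  stopifnot(!anyNA(per_image$dice))  # every image validated exactly once
  per_fold <- do.call(rbind, lapply(seq_len(config$n_folds), function(f) {
    d <- per_image[per_image$fold == f, ]
    data.frame(fold = f, n = nrow(d), threshold = thresholds[f],
               mean_dice = mean(d$dice), sd_dice = sd(d$dice),
               mean_iou = mean(d$iou), sd_iou = sd(d$iou))
  }))
  structure(list(
    per_image = per_image, per_fold = per_fold,
    mean_dice = mean(per_fold$mean_dice), sd_dice = sd(per_image$dice),
    mean_iou = mean(per_fold$mean_iou), sd_iou = sd(per_image$iou),
    fold_assignment = data.frame(participant = names(fold_of_key),
                                 fold = unname(fold_of_key)),
    config = config
  ), class = "seg_cv")
}

#' @export
print.seg_cv <- function(x, ...) {
  cat(sprintf(
    "grouped %d-fold cross-validation over %d images (%d participants)\n",
    x$config$n_folds, nrow(x$per_image),
    nrow(x$fold_assignment)))
  cat(sprintf("  Dice %.3f +/- %.3f   IoU %.3f +/- %.3f\n",
              x$mean_dice, x$sd_dice, x$mean_iou, x$sd_iou))
  invisible(x)
}
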