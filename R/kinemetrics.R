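new_tip_trajectory <- function(time, displacement, flag, baseline_x,
                               mm_per_px, fps) {
  df <- data.frame(time = time, displacement = displacement, flag = flag,
                   stringsAsFactors = FALSE)
  attr(df, "baseline_x") <- baseline_x
  attr(df, "mm_per_px") <- mm_per_px
  attr(df, "fps") <- fps
  class(df) <- c("tip_trajectory", "data.frame")
  df
}

#' Extract the lateral tongue-tip displacement series from binary masks
#'
#' The tongue tip is operationally the most lateral point of the
#' segmented binary mask along the horizontal axis: per frame the
#' leftmost and rightmost mask columns are candidates and the one
#' farther from the clip-wide baseline (the median mask-centroid column)
#' wins; equidistant candidates resolve to the leftmost. Displacement is
#' `(x_tip - baseline) * mm_per_px`, signed, rightward positive. Frames
#' with an empty mask are linearly interpolated from their neighbours and
#' flagged `"interpolated"`; runs of missing frames longer than
#' `max_gap` fail quality control.
#'
#' @param masks `[H,W,T]` array (logical or 0/1) or list of binary
#'   matrices, one per frame.
#' @param fps Frames per second (> 0).
#' @param mm_per_px Spatial calibration (mm per pixel, > 0). Must be
#'   supplied; it is never inferred from the image content.
#' @param max_gap Maximum tolerated run of consecutive empty-mask frames.
#' @return A `tip_trajectory`: data frame with `time` (s), `displacement`
#'   (mm) and `flag` (`"observed"` or `"interpolated"`), with the pixel
#'   baseline, `mm_per_px` and `fps` stored as attributes.
#' @export
extract_tip_series <- function(masks, fps, mm_per_px, max_gap = 10L) {
  check_number(fps, "fps", lower = 1e-9)
  check_number(mm_per_px, "mm_per_px", lower = 1e-9)
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(k) masks[, , k])
  if (!is.list(masks) || length(masks) == 0)
    stop_param("`masks` must be a [H,W,T] array or non-empty list of matrices")
  n <- length(masks)
  left <- right <- centroid <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    cs <- colSums(masks[[k]] > 0.5)
    nz <- which(cs > 0)
    if (length(nz) == 0) next
    left[k] <- nz[1]
    right[k] <- nz[length(nz)]
    centroid[k] <- sum(cs[nz] * nz) / sum(cs[nz])
  }
  obs <- !is.na(left)
  if (!any(obs)) stop_param("all masks are empty; no tongue to track")
  gaps <- rle(!obs)
  if (any(gaps$lengths[gaps$values] > max_gap))
    stop_param("run of %d empty-mask frames exceeds the %d-frame limit",
               max(gaps$lengths[gaps$values]), max_gap)
  baseline <- median(centroid[obs])
  tip <- ifelse(abs(left - baseline) >= abs(right - baseline), left, right)
  disp <- (tip - baseline) * mm_per_px
  # linear interpolation over interior gaps; edge gaps take the nearest
  # observed value
  if (any(!obs)) {
    disp <- stats::approx(which(obs), disp[obs], xout = seq_len(n),
                          rule = 2)$y
  }
  new_tip_trajectory(
    time = (seq_len(n) - 1) / fps, displacement = disp,
    flag = ifelse(obs, "observed", "interpolated"),
    baseline_x = baseline * mm_per_px, mm_per_px = mm_per_px, fps = fps)
}

# centred moving average with edge replication
smooth_ma <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1) return(x)
  n <- length(x)
  pad_l <- (window - 1) %/% 2
  pad_r <- window - 1 - pad_l
  xp <- c(rep(x[1], pad_l), x, rep(x[n], pad_r))
  cs <- cumsum(xp)
  (cs[window:(n + window - 1)] - c(0, cs[seq_len(n - 1)])) / window
}

#' Count complete lateral oscillation cycles
#'
#' Mean-centres the (smoothed) displacement signal and applies a
#' hysteresis state machine with thresholds at `+/- h`,
#' `h = hysteresis_frac * max(|d|)`: each excursion beyond a threshold on
#' the side opposite to the previous excursion is an alternation, and
#' every two alternations -- one left excursion and one right excursion --
#' complete one cycle. Partial cycles are discarded.
#'
#' @param trajectory A `tip_trajectory`, or a numeric displacement vector
#'   (then `fps` must be given).
#' @param window Two-element numeric `c(start, end)` in seconds; the
#'   trajectory must cover it.
#' @param hysteresis_frac Threshold as a fraction of the maximum absolute
#'   centred displacement.
#' @param smooth_window Centred moving-average width (frames) applied
#'   before detection; 5 frames (~167 ms at 30 fps) suppresses
#'   single-frame segmentation jitter.
#' @param fps Frames per second when `trajectory` is a bare vector.
#' @return Integer number of complete cycles.
#' @export
count_cycles <- function(trajectory, window = NULL, hysteresis_frac = 0.2,
                         smooth_window = 5L, fps = NULL) {
  if (inherits(trajectory, "tip_trajectory")) {
    tt <- trajectory$time
    d <- trajectory$displacement
    fps <- attr(trajectory, "fps")
  } else {
    if (is.null(fps)) stop_param("`fps` is required for a bare vector")
    d <- as.numeric(trajectory)
    tt <- (seq_along(d) - 1) / fps
  }
  if (!is.null(window)) {
    if (window[2] - 1 / fps > max(tt) + 1e-9 || window[1] < min(tt) - 1e-9)
      stop_param("analysis window [%g, %g] extends beyond the trajectory",
                 window[1], window[2])
    keep <- tt >= window[1] - 1e-9 & tt < window[2] - 1e-9
    d <- d[keep]
  }
  scale0 <- max(abs(d), 1)
  d <- smooth_ma(d, smooth_window)
  d <- d - mean(d)
  h <- hysteresis_frac * max(abs(d))
  # constant signals leave only floating-point residue after centring
  if (h <= 1e-9 * scale0) return(0L)
  state <- 0L
  alternations <- 0L
  for (x in d) {
    if (x > h && state != 1L) {
      alternations <- alternations + 1L
      state <- 1L
    } else if (x < -h && state != -1L) {
      alternations <- alternations + 1L
      state <- -1L
    }
  }
  as.integer(alternations %/% 2L)
}

#' Kinematic features of a tongue-tip trajectory
#'
#' Computes the task metrics over a `duration`-second scoring window:
#' `frequency = n_cycles / duration` (complete cycles only),
#' `max_amplitude = max(|d|)` of the raw displacement in the window (mm),
#' and `normalized_frequency = frequency / max_amplitude` (Hz/mm). The
#' window starts at movement onset (first smoothed sample beyond the
#' hysteresis threshold) when enough signal remains, otherwise at the
#' clip start (with a warning when the foregone onset was later than
#' 0.5 s). Amplitudes below `amp_guard` abort with an error, because
#' near-zero amplitudes would artificially inflate the normalized ratio.
#'
#' @param trajectory A `tip_trajectory`.
#' @param duration Scoring window length in seconds (task standard: 5).
#' @param amp_guard Minimum acceptable maximum amplitude (mm).
#' @param hysteresis_frac,smooth_window Passed to [count_cycles()].
#' @return An object of class `kin_features`: list with `n_cycles`,
#'   `duration`, `frequency` (Hz), `max_amplitude` (mm),
#'   `normalized_frequency` (Hz/mm).
#' @export
compute_features <- function(trajectory, duration = 5, amp_guard = 1,
                             hysteresis_frac = 0.2, smooth_window = 5L) {
  stopifnot(inherits(trajectory, "tip_trajectory"))
  fps <- attr(trajectory, "fps")
  tt <- trajectory$time
  d <- trajectory$displacement
  if (max(tt) + 1 / fps < duration - 1e-9)
    stop_param("trajectory (%.2f s) is shorter than the %g-s scoring window",
               max(tt) + 1 / fps, duration)
  ds <- smooth_ma(d, smooth_window)
  ds <- ds - mean(ds)
  h <- hysteresis_frac * max(abs(ds))
  onset_idx <- which(abs(ds) > h)[1]
  t0 <- if (!is.na(onset_idx)) tt[onset_idx] else tt[1]
  if (t0 + duration - 1 / fps > max(tt) + 1e-9) {
    if (t0 > 0.5)
      warning(sprintf(
        "movement onset at %.2f s leaves less than %g s; scoring from clip start",
        t0, duration))
    t0 <- tt[1]
  }
  win <- c(t0, t0 + duration)
  n_cyc <- count_cycles(trajectory, window = win,
                        hysteresis_frac = hysteresis_frac,
                        smooth_window = smooth_window)
  keep <- tt >= win[1] - 1e-9 & tt < win[2] - 1e-9
  amp <- max(abs(d[keep]))  # displacement is already baseline-relative
  if (amp < amp_guard)
    stop_param("maximum amplitude %.3f mm is below the %.1f mm guard", amp,
               amp_guard)
  structure(list(n_cycles = n_cyc, duration = duration,
                 frequency = n_cyc / duration, max_amplitude = amp,
                 normalized_frequency = (n_cyc / duration) / amp),
            class = "kin_features")
}

#' Average the kinematic features of two trials
#'
#' Subjects perform the task twice; the subject-level value is the mean
#' of both trials (feature-wise; the averaged cycle count can be
#' non-integer). A missing second trial falls back to the single trial
#' with a warning.
#'
#' @param trial1,trial2 `kin_features` objects (`trial2` may be `NULL`).
#' @return A `kin_features` object.
#' @export
average_trials <- function(trial1, trial2 = NULL) {
  stopifnot(inherits(trial1, "kin_features"))
  if (is.null(trial2)) {
    warning("second trial missing; using the single available trial")
    return(trial1)
  }
  stopifnot(inherits(trial2, "kin_features"))
  structure(list(
    n_cycles = (trial1$n_cycles + trial2$n_cycles) / 2,
    duration = (trial1$duration + trial2$duration) / 2,
    frequency = (trial1$frequency + trial2$frequency) / 2,
    max_amplitude = (trial1$max_amplitude + trial2$max_amplitude) / 2,
    normalized_frequency =
      (trial1$normalized_frequency + trial2$normalized_frequency) / 2
  ), class = "kin_features")
}

#' @export
print.kin_features <- function(x, ...) {
  cat(sprintf(
    "kinematic features: %.1f cycles / %g s -> %.2f Hz; A_max %.2f mm; normalized %.3f Hz/mm\n",
    x$n_cycles, x$duration, x$frequency, x$max_amplitude,
    x$normalized_frequency))
  invisible(x)
}

#' @export
print.tip_trajectory <- function(x, ...) {
  cat(sprintf(
    "tip trajectory: %d frames at %g fps (%.2f s), %d interpolated\n",
    nrow(x), attr(x, "fps"), max(x$time) + 1 / attr(x, "fps"),
    sum(x$flag == "interpolated")))
  invisible(x)
}
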