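#' Specification of a synthetic tongue-lateralization clip
#'
#' Describes one simulated task recording: acquisition parameters
#' (frame rate, duration, geometry, spatial calibration), the true
#' oscillation (frequency, one-sided amplitude in mm, phase), tongue
#' shape, and nuisance terms (pixel noise, illumination jitter, residual
#' jaw drift for participants who do not keep the jaw perfectly still).
#' Identical specs with identical seeds render bit-identical clips.
#'
#' @param fps Frames per second (> 0); smartphone default 30.
#' @param duration Clip length in seconds (>= 5; the task lasts at least
#'   five seconds).
#' @param width,height Frame size in pixels.
#' @param mm_per_px Spatial calibration, millimetres per pixel. The
#'   default 0.25 at a 256-px working width corresponds to a ~6.4 cm
#'   field of view over the perioral region.
#' @param freq_true True lateral oscillation frequency in Hz (>= 0).
#' @param amp_true True one-sided lateral excursion in mm (>= 0).
#' @param phase Oscillation phase in radians.
#' @param tongue_axes Ellipse semi-axes (mm) of the tongue blob, c(x, y).
#' @param boundary_pert Maximum coefficient of the smooth (low-order
#'   cosine) boundary perturbation; 0 renders a perfect ellipse.
#' @param noise_sd Additive pixel-noise SD in [0,1] intensity units.
#' @param illum_jitter SD of the per-frame relative illumination gain.
#' @param jaw_drift_amp,jaw_drift_freq Amplitude (mm) and frequency (Hz)
#'   of a slow sinusoidal jaw drift superimposed on the tongue motion.
#' @param seed Integer seed.
#' @return An object of class `clip_spec`.
#' @export
clip_spec <- function(fps = 30, duration = 5, width = 256L, height = 192L,
                      mm_per_px = 0.25, freq_true = 2, amp_true = 10,
                      phase = 0, tongue_axes = c(12, 9),
                      boundary_pert = 0.05, noise_sd = 0.02,
                      illum_jitter = 0.05, jaw_drift_amp = 0,
                      jaw_drift_freq = 0.3, seed = 1L) {
  check_number(fps, "fps", lower = 1e-9)
  check_number(duration, "duration", lower = 5)
  check_number(mm_per_px, "mm_per_px", lower = 1e-9)
  check_number(freq_true, "freq_true", lower = 0)
  check_number(amp_true, "amp_true", lower = 0)
  check_number(boundary_pert, "boundary_pert", lower = 0, upper = 0.2)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(jaw_drift_amp, "jaw_drift_amp", lower = 0)
  if (length(tongue_axes) != 2 || any(tongue_axes <= 0))
    stop_param("`tongue_axes` must be two positive semi-axes in mm")
  structure(list(fps = fps, duration = duration,
                 width = as.integer(width), height = as.integer(height),
                 mm_per_px = mm_per_px, freq_true = freq_true,
                 amp_true = amp_true, phase = phase,
                 tongue_axes = tongue_axes, boundary_pert = boundary_pert,
                 noise_sd = noise_sd,
                 illum_jitter = illum_jitter,
                 jaw_drift_amp = jaw_drift_amp,
                 jaw_drift_freq = jaw_drift_freq,
                 seed = as.integer(seed)),
            class = "clip_spec")
}

# Rasterize one tongue scene. Coordinates: pixel (1,1) top-left, x (column
# index) increases rightward; displacement sign follows x.
# Returns list(img [H,W,3] in [0,1] or NULL, mask [H,W] logical).
render_scene <- function(width, height, cx, cy, a_px, b_px, angle,
                         pert_c, pert_psi, col_skin, col_mouth, col_tongue,
                         mouth_box, gain = 1, noise = NULL, blur_sigma = 0,
                         draw_image = TRUE) {
  X <- matrix(seq_len(width), height, width, byrow = TRUE)
  Y <- matrix(seq_len(height), height, width)
  dx <- X - cx
  dy <- Y - cy
  ca <- cos(angle); sa <- sin(angle)
  u <- (ca * dx + sa * dy) / a_px
  v <- (-sa * dx + ca * dy) / b_px
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rb <- 1
  for (k in seq_along(pert_c))
    rb <- rb + pert_c[k] * cos((k + 1) * theta + pert_psi[k])
  mask <- rho <= rb
  if (!draw_image) return(list(img = NULL, mask = mask))
  img <- array(0, c(height, width, 3))
  in_mouth <- X >= mouth_box[1] & X <= mouth_box[2] &
    Y >= mouth_box[3] & Y <= mouth_box[4]
  for (ch in 1:3) {
    plane <- matrix(col_skin[ch], height, width)
    plane[in_mouth] <- col_mouth[ch]
    plane[mask] <- col_tongue[ch]
    img[, , ch] <- plane
  }
  img <- img * gain
  if (!is.null(noise)) img <- img + noise
  img <- clamp(img, 0, 1)
  if (blur_sigma > 0) img <- clamp(EBImage::gblur(img, sigma = blur_sigma), 0, 1)
  img
  list(img = img, mask = mask)
}

#' Render a synthetic tongue-lateralization clip
#'
#' Draws an elliptical tongue (with a smooth per-clip boundary
#' perturbation) over a two-tone face/mouth background. The tongue centre
#' follows `x(t) = A * sin(2*pi*f*t + phase)` plus any configured jaw
#' drift. Per-frame ground-truth masks cover exactly the rendered tongue
#' pixels.
#'
#' @param spec A [clip_spec()].
#' @param return_frames If `FALSE`, only masks and ground truth are
#'   produced (much faster; rendering noise is skipped).
#' @return A list of class `synth_clip` with elements `frames`
#'   (`[H,W,3,T]` array or `NULL`), `truth` (class `clip_truth`: `masks`
#'   `[H,W,T]` logical array; `tip_x_true`, the baseline-relative mm
#'   displacement of the most lateral shape point per frame, i.e. what a
#'   perfect mask tracker measures; `centre_x_true`, the sinusoidal
#'   centre displacement; `lateral_extent`; `n_cycles_true`;
#'   `normfreq_true`), and `spec`.
#' @export
render_clip <- function(spec, return_frames = TRUE) {
  stopifnot(inherits(spec, "clip_spec"))
  set.seed(spec$seed)
  n_frames <- as.integer(round(spec$fps * spec$duration))
  tt <- (seq_len(n_frames) - 1) / spec$fps
  mmpp <- spec$mm_per_px
  a_px <- spec$tongue_axes[1] / mmpp
  b_px <- spec$tongue_axes[2] / mmpp
  cx0 <- spec$width / 2
  cy0 <- spec$height * 0.55
  disp_mm <- spec$amp_true * sin(2 * pi * spec$freq_true * tt + spec$phase) +
    spec$jaw_drift_amp * sin(2 * pi * spec$jaw_drift_freq * tt)
  # per-clip static shape perturbation and colours
  pert_c <- runif(3, 0, spec$boundary_pert)
  pert_psi <- runif(3, 0, 2 * pi)
  # lateral extents and centroid offset of the continuous shape (mm),
  # used for the ground-truth tip trajectory
  th <- seq(0, 2 * pi, length.out = 4096L)
  rb_th <- 1
  for (k in seq_along(pert_c))
    rb_th <- rb_th + pert_c[k] * cos((k + 1) * th + pert_psi[k])
  bx <- spec$tongue_axes[1] * rb_th * cos(th)
  ext_right <- max(bx)
  ext_left <- -min(bx)
  dth <- th[2] - th[1]
  area_n <- sum(rb_th^2 / 2) * dth
  centroid_mm <- spec$tongue_axes[1] * sum(rb_th^3 / 3 * cos(th)) * dth / area_n
  col_skin <- c(0.80, 0.62, 0.52) + rnorm(3, 0, 0.02)
  col_mouth <- c(0.24, 0.10, 0.10) + rnorm(3, 0, 0.02)
  col_tongue <- c(0.78, 0.30, 0.34) + rnorm(3, 0, 0.02)
  reach <- (spec$amp_true + spec$jaw_drift_amp) / mmpp + a_px * 1.1
  mouth_box <- c(cx0 - reach - 6, cx0 + reach + 6,
                 cy0 - b_px * 1.2 - 6, cy0 + b_px * 1.2 + 6)
  gains <- 1 + rnorm(n_frames, 0, spec$illum_jitter)
  masks <- array(FALSE, c(spec$height, spec$width, n_frames))
  frames <- if (return_frames)
    array(0, c(spec$height, spec$width, 3, n_frames)) else NULL
  for (k in seq_len(n_frames)) {
    noise <- if (return_frames && spec$noise_sd > 0)
      array(rnorm(spec$height * spec$width, 0, spec$noise_sd),
            c(spec$height, spec$width, 3)) else NULL
    sc <- render_scene(spec$width, spec$height,
                       cx0 + disp_mm[k] / mmpp, cy0, a_px, b_px, 0,
                       pert_c, pert_psi, col_skin, col_mouth, col_tongue,
                       mouth_box, gains[k], noise,
                       draw_image = return_frames)
    masks[, , k] <- sc$mask
    if (return_frames) frames[, , , k] <- sc$img
  }
  n_cycles_true <- if (spec$amp_true == 0) 0L else
    as.integer(floor(spec$freq_true * min(spec$duration, 5)))
  # ground-truth tip series as the most lateral boundary point relative
  # to the clip-wide baseline (median shape centroid), mirroring the
  # tracking definition: the farther of the two lateral extremes wins,
  # leftmost on ties
  baseline_mm <- centroid_mm + median(disp_mm)
  x_right <- disp_mm + ext_right
  x_left <- disp_mm - ext_left
  use_left <- abs(x_left - baseline_mm) >= abs(x_right - baseline_mm)
  tip_x_true <- ifelse(use_left, x_left, x_right) - baseline_mm
  truth <- structure(list(
    masks = masks,
    tip_x_true = tip_x_true,
    centre_x_true = disp_mm,
    lateral_extent = c(left = ext_left, right = ext_right),
    n_cycles_true = n_cycles_true,
    normfreq_true = if (spec$amp_true > 0) spec$freq_true / spec$amp_true
    else NA_real_
  ), class = "clip_truth")
  structure(list(frames = frames, truth = truth, spec = spec),
            class = "synth_clip")
}

#' @export
print.synth_clip <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "synthetic clip: %.0f fps x %.1f s (%d frames), %dx%d px, %.3f mm/px\n",
    s$fps, s$duration, dim(x$truth$masks)[3], s$width, s$height, s$mm_per_px))
  cat(sprintf("  true: f = %.2f Hz, A = %.1f mm, %d complete cycles\n",
              s$freq_true, s$amp_true, x$truth$n_cycles_true))
  invisible(x)
}
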