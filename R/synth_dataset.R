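#' Generate a synthetic tongue segmentation training set
#'
#' Produces image/mask pairs emulating a heterogeneous collection of
#' annotated tongue photographs: tongue shape, pose, scale, colour,
#' illumination, blur, noise and background tones are all randomized.
#' Several images share a participant key (a participant contributes a
#' consistent tongue shape and colouring across their images), so the set
#' exercises participant-grouped cross-validation. No diagnostic label is
#' attached to any image.
#'
#' @param n Number of image/mask pairs (>= 0).
#' @param size Square image side in pixels.
#' @param images_per_participant Average number of images sharing one
#'   participant key.
#' @param blur_max Maximum Gaussian blur sigma (pixels) applied to images.
#' @param noise_sd Pixel noise SD in intensity units.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `seg_dataset`: list with `images` (list of
#'   `[size,size,3]` arrays in `[0,1]`), `masks` (list of binary
#'   matrices) and `participant` (character vector of keys).
#' @export
generate_segmentation_dataset <- function(n, size = 128L,
                                          images_per_participant = 4,
                                          blur_max = 1.2, noise_sd = 0.03,
                                          seed = 1L) {
  check_number(n, "n", lower = 0)
  n <- as.integer(n)
  size <- as.integer(size)
  set.seed(derive_seed(seed, "segdata"))
  images <- vector("list", n)
  masks <- vector("list", n)
  participant <- character(n)
  if (n == 0)
    return(structure(list(images = images, masks = masks,
                          participant = participant, size = size),
                     class = "seg_dataset"))
  n_part <- max(1L, as.integer(ceiling(n / images_per_participant)))
  keys <- sprintf("p%03d", seq_len(n_part))
  # participant-level appearance: shape perturbation, colouring
  part <- lapply(seq_len(n_part), function(i) list(
    pert_c = runif(3, 0, 0.08),
    pert_psi = runif(3, 0, 2 * pi),
    col_skin = clamp(c(0.80, 0.62, 0.52) + rnorm(3, 0, 0.05), 0, 1),
    col_mouth = clamp(c(0.24, 0.10, 0.10) + rnorm(3, 0, 0.04), 0, 1),
    col_tongue = clamp(c(0.78, 0.30, 0.34) +
                         c(rnorm(1, 0, 0.06), rnorm(2, 0, 0.04)), 0, 1),
    aspect = runif(1, 0.6, 0.9)
  ))
  assignment <- rep(seq_len(n_part), length.out = n)
  for (k in seq_len(n)) {
    pp <- part[[assignment[k]]]
    a_px <- runif(1, 0.16, 0.30) * size
    b_px <- a_px * pp$aspect
    cx <- size / 2 + runif(1, -0.15, 0.15) * size
    cy <- size * 0.55 + runif(1, -0.12, 0.12) * size
    angle <- runif(1, -0.35, 0.35)
    mouth_w <- a_px * runif(1, 1.4, 2.2)
    mouth_h <- b_px * runif(1, 1.3, 1.8)
    mouth_box <- c(cx - mouth_w, cx + mouth_w, cy - mouth_h, cy + mouth_h)
    gain <- 1 + rnorm(1, 0, 0.10)
    noise <- array(rnorm(size * size, 0, noise_sd), c(size, size, 3))
    sc <- render_scene(size, size, cx, cy, a_px, b_px, angle,
                       pp$pert_c, pp$pert_psi, pp$col_skin, pp$col_mouth,
                       pp$col_tongue, mouth_box, gain, noise,
                       blur_sigma = runif(1, 0, blur_max))
    images[[k]] <- sc$img
    masks[[k]] <- matrix(as.numeric(sc$mask), size, size)
    participant[k] <- keys[assignment[k]]
  }
  structure(list(images = images, masks = masks, participant = participant,
                 size = size),
            class = "seg_dataset")
}

#' @export
print.seg_dataset <- function(x, ...) {
  cat(sprintf("synthetic segmentation dataset: %d image/mask pairs, %dx%d px, %d participants\n",
              length(x$images), x$size, x$size, length(unique(x$participant))))
  invisible(x)
}
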