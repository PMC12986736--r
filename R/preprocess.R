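#' Preprocess an image for segmentation
#'
#' Resizes to the square working resolution (bilinear) and normalizes
#' pixel intensities to the `[0, 1]` range: 8-bit-scaled inputs (values
#' above 1) are divided by 255, then values are clipped to `[0, 1]`.
#'
#' @param image Numeric matrix `[H,W]` or array `[H,W,C]`.
#' @param size Target side length in pixels.
#' @return Array `[size, size, C]` (grayscale inputs gain a channel
#'   dimension of 1) with values in `[0, 1]`.
#' @export
preprocess_image <- function(image, size = 256L) {
  if (is.null(dim(image)) || any(dim(image)[1:2] < 1) || length(image) == 0)
    stop_param("`image` must be a non-empty matrix or array")
  size <- as.integer(size)
  x <- image
  if (max(x) > 1) x <- x / 255
  x <- clamp(x, 0, 1)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  if (!identical(dim(x)[1:2], c(size, size))) {
    x <- EBImage::resize(x, w = size, h = size)
    x <- clamp(x, 0, 1)  # bilinear interpolation stays in range; be strict
  }
  x <- array(x, c(size, size, dim(x)[3]))
  x
}

#' Preprocess a binary mask
#'
#' Nearest-neighbour resize so the mask stays strictly binary.
#'
#' @param mask Binary matrix `[H,W]`.
#' @param size Target side length in pixels.
#' @return Binary (0/1) matrix `[size, size]`.
#' @export
preprocess_mask <- function(mask, size = 256L) {
  if (is.null(dim(mask)) || length(mask) == 0)
    stop_param("`mask` must be a non-empty matrix")
  size <- as.integer(size)
  m <- (mask > 0.5) * 1
  if (!identical(dim(m), c(size, size))) {
    m <- EBImage::resize(m, w = size, h = size, filter = "none")
  }
  matrix((m > 0.5) * 1, size, size)
}
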