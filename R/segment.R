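#' Segment the tongue in every frame of a clip
#'
#' Preprocesses each frame to the model input size, predicts a
#' probability map, thresholds it, and maps the binary mask back to the
#' source frame resolution (nearest-neighbour). Frames whose mask is
#' (near-)empty are flagged so downstream tip tracking can treat them as
#' missing.
#'
#' @param model A trained `unetpp_model`.
#' @param frames `[H,W,3,T]` array or list of `[H,W,3]` arrays.
#' @param threshold Binarization threshold; defaults to the model's
#'   configured value.
#' @param min_area Masks with fewer foreground pixels (at model
#'   resolution) are flagged empty.
#' @return List with `masks` (`[H,W,T]` logical array at the source
#'   resolution) and `empty` (logical flag per frame).
#' @export
segment_clip <- function(model, frames, threshold = NULL, min_area = 10L) {
  stopifnot(inherits(model, "unetpp_model"))
  if (!isTRUE(model$trained))
    stop_param("model is untrained; train or load a checkpoint first")
  threshold <- threshold %||% model$config$threshold
  if (is.array(frames) && length(dim(frames)) == 4)
    frames <- lapply(seq_len(dim(frames)[4]), function(k) frames[, , , k])
  n <- length(frames)
  if (n == 0) stop_param("no frames to segment")
  h0 <- dim(frames[[1]])[1]
  w0 <- dim(frames[[1]])[2]
  size <- model$config$input_size
  masks <- array(FALSE, c(h0, w0, n))
  empty <- logical(n)
  batch <- 8L
  k <- 1L
  while (k <= n) {
    ids <- k:min(k + batch - 1L, n)
    xb <- stack_batch(lapply(frames[ids], preprocess_image, size = size),
                      channels = model$in_channels)
    prob <- unetpp_forward(model, xb, keep_cache = FALSE)$logits
    prob <- 1 / (1 + exp(-prob))
    for (j in seq_along(ids)) {
      m <- prob[, , 1, j] >= threshold
      empty[ids[j]] <- sum(m) < min_area
      back <- EBImage::resize(matrix(as.numeric(m), size, size),
                              w = h0, h = w0, filter = "none")
      masks[, , ids[j]] <- back > 0.5
    }
    k <- k + batch
  }
  list(masks = masks, empty = empty)
}
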