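#' Dice coefficient and intersection-over-union of two binary masks
#'
#' `Dice = 2|A n B| / (|A| + |B|)` and `IoU = |A n B| / |A u B|`.
#' When both masks are empty the overlap is perfect by convention
#' (both metrics 1); when exactly one is empty both metrics are 0.
#' The identity `dice = 2 * iou / (1 + iou)` holds exactly.
#'
#' @param pred_mask,true_mask Binary (logical or 0/1) matrices of equal
#'   shape.
#' @return A list with elements `dice` and `iou`.
#' @export
dice_iou <- function(pred_mask, true_mask) {
  a <- pred_mask > 0.5
  b <- true_mask > 0.5
  if (!identical(dim(a), dim(b))) stop_param("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(list(dice = 1, iou = 1))
  if (na == 0 || nb == 0) return(list(dice = 0, iou = 0))
  inter <- sum(a & b)
  list(dice = 2 * inter / (na + nb), iou = inter / (na + nb - inter))
}
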