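#' Combined binary cross-entropy and soft-Dice loss
#'
#' `loss = w_bce * BCE(p, g) + w_dice * (1 - (2*sum(p*g) + eps) /
#' (sum(p) + sum(g) + eps))`. BCE is averaged over all pixels; the
#' soft-Dice term is computed per image and averaged over the batch.
#' The smoothing constant `eps = 1` stabilizes the ratio on empty masks.
#'
#' @param pred_probs Predicted probabilities in `(0,1)`; matrix, `[H,W,1]`
#'   or `[H,W,1,B]` array.
#' @param true_mask Binary ground truth of the same shape.
#' @param w_bce,w_dice Term weights.
#' @param eps Soft-Dice smoothing constant.
#' @return Scalar loss.
#' @export
loss_bce_softdice <- function(pred_probs, true_mask, w_bce = 1, w_dice = 1,
                              eps = 1) {
  p <- as_batch1(pred_probs)
  g <- as_batch1(true_mask)
  if (!identical(dim(p), dim(g)))
    stop_param("prediction and mask shapes differ")
  pc <- clamp(p, 1e-7, 1 - 1e-7)
  bce <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  B <- dim(p)[4]
  dice <- mean(vapply(seq_len(B), function(b) {
    pb <- p[, , 1, b]; gb <- g[, , 1, b]
    1 - (2 * sum(pb * gb) + eps) / (sum(pb) + sum(gb) + eps)
  }, numeric(1)))
  w_bce * bce + w_dice * dice
}

# coerce matrix / [H,W,1] / [H,W,1,B] to [H,W,1,B]
as_batch1 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_param("expected a matrix or array")
  if (length(d) == 2) d <- c(d, 1L, 1L)
  if (length(d) == 3) d <- c(d, 1L)
  array(x, d)
}

# Loss and its gradient with respect to logits (numerically stable BCE).
loss_grad_from_logits <- function(logits, g, w_bce = 1, w_dice = 1, eps = 1) {
  z <- logits
  p <- 1 / (1 + exp(-z))
  n_all <- length(z)
  B <- dim(z)[4]
  # BCE from logits: max(z,0) - z*g + log1p(exp(-|z|))
  bce <- mean(pmax(z, 0) - z * g + log1p(exp(-abs(z))))
  d_bce <- (p - g) / n_all
  dice_terms <- numeric(B)
  d_dice <- array(0, dim(z))
  for (b in seq_len(B)) {
    pb <- p[, , 1, b]; gb <- g[, , 1, b]
    s1 <- sum(pb * gb); s2 <- sum(pb) + sum(gb)
    dice_terms[b] <- 1 - (2 * s1 + eps) / (s2 + eps)
    dD_dp <- -(2 * gb * (s2 + eps) - (2 * s1 + eps)) / (s2 + eps)^2
    d_dice[, , 1, b] <- dD_dp * pb * (1 - pb) / B
  }
  list(loss = w_bce * bce + w_dice * mean(dice_terms),
       d_logits = w_bce * d_bce + w_dice * d_dice)
}
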