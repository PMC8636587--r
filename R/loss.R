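#' Combined soft-Dice and cross-entropy loss
#'
#' Training loss of the segmentation network:
#' `sum_c (1 - softDice_c) + CE`, where the soft Dice term runs over the
#' foreground classes (femur, tibia, fibula) present in the target —
#' `softDice_c = 2 sum(p_c t_c) / (sum p_c + sum t_c + eps)` with
#' `eps = 1e-5` — and CE is the voxel-averaged categorical cross-entropy
#' over all classes. When the target contains no foreground class the loss
#' equals its cross-entropy value alone. A perfect one-hot prediction
#' drives the loss to 0 as `eps -> 0`.
#'
#' @param probabilities array (X, Y, Z, classes), normalized per voxel.
#' @param target an `lt_mask` or integer array of class codes, aligned
#'   with `probabilities`.
#' @param eps soft-Dice stabilizer.
#' @return Scalar loss.
#' @export
combined_loss <- function(probabilities, target, eps = 1e-5) {
  t_arr <- if (is_lt_mask(target)) target$data else target
  d <- dim(probabilities)
  if (length(d) != 4L || !all(d[1:3] == dim(t_arr)))
    stop("probabilities and target shapes are misaligned")
  n <- prod(d[1:3])
  P <- matrix(probabilities, n, d[4])
  tv <- as.integer(t_arr)
  ce <- -mean(log(pmax(P[cbind(seq_len(n), tv + 1L)], 1e-12)))
  dice_sum <- 0
  for (c in seq_len(d[4] - 1L)) {       # foreground codes 1..classes-1
    tc <- tv == c
    if (!any(tc)) next
    dice_sum <- dice_sum +
      (1 - 2 * sum(P[tc, c + 1L]) / (sum(P[, c + 1L]) + sum(tc) + eps))
  }
  dice_sum + ce
}

# Loss and d(loss)/d(logits) in one pass (log-softmax for stability).
loss_grad_logits <- function(logits, target, eps = 1e-5) {
  t_arr <- if (is_lt_mask(target)) target$data else target
  d <- dim(logits)
  if (!all(d[1:3] == dim(t_arr)))
    stop("logits and target shapes are misaligned")
  n <- prod(d[1:3])
  L <- matrix(logits, n, d[4])
  L <- L - apply(L, 1, max)
  lse <- log(rowSums(exp(L)))
  logp <- L - lse
  P <- exp(logp)
  tv <- as.integer(t_arr)
  onehot_idx <- cbind(seq_len(n), tv + 1L)
  ce <- -mean(logp[onehot_idx])
  gp <- matrix(0, n, d[4])              # d(dice terms)/d(prob)
  dice_sum <- 0
  for (c in seq_len(d[4] - 1L)) {
    tc <- tv == c
    if (!any(tc)) next
    Sc <- sum(P[tc, c + 1L])
    den <- sum(P[, c + 1L]) + sum(tc) + eps
    dice_sum <- dice_sum + (1 - 2 * Sc / den)
    gp[, c + 1L] <- gp[, c + 1L] - 2 * (as.numeric(tc) * den - Sc) / den^2
  }
  # chain dice grads through softmax, add the CE softmax gradient
  g <- P * (gp - rowSums(gp * P))
  g[onehot_idx] <- g[onehot_idx] - 1 / n
  g <- g + P / n
  list(loss = dice_sum + ce, grad = array(g, d))
}
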