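#' Loss weights and SSIM settings
#'
#' The per-output composite loss is `L = L1 + alpha * L_ssim`; the
#' lesion-attention loss adds the composite loss recomputed over the lesion
#' region, `l = L + beta * L_masked`; the deep-supervision total is
#' `L_total = sum_i w_side[i] * l_side[i] + w_final * l_final` over the six
#' side outputs and the final output.
#'
#' SSIM is computed over sliding `ssim_window` x `ssim_window` windows
#' (valid positions only) with stability constants `c1 = (k1 R)^2`,
#' `c2 = (k2 R)^2` where `R` is the dynamic range of the target.
#'
#' @param alpha SSIM-loss weight (default 0.5).
#' @param beta lesion-region weight (default 100).
#' @param w_side six per-side-output weights (default all 1).
#' @param w_final final-output weight (default 1).
#' @param ssim_window odd window size (default 11).
#' @param ssim_k1,ssim_k2 constants of the SSIM stabilizers.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.5, beta = 100, w_side = rep(1, 6),
                         w_final = 1, ssim_window = 11,
                         ssim_k1 = 0.01, ssim_k2 = 0.03) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (length(w_side) != 6L) stop("w_side must have 6 entries")
  if (!all(is.finite(c(alpha, beta, w_side, w_final)))) stop("weights must be finite")
  if (ssim_window %% 2 == 0) stop("ssim_window must be odd")
  structure(list(alpha = alpha, beta = beta, w_side = as.numeric(w_side),
                 w_final = w_final, ssim_window = as.integer(ssim_window),
                 ssim_k1 = ssim_k1, ssim_k2 = ssim_k2),
            class = "loss_weights")
}

to4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("inputs must be matrices or arrays")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

check_pair <- function(pred, target, mask = NULL) {
  if (!identical(dim(pred), dim(target)))
    stop("pred and target shapes differ")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(pred))) stop("mask shape differs from pred")
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  }
  invisible(NULL)
}

ssim_constants <- function(target, weights) {
  r <- diff(range(target))
  if (r == 0) r <- 1 # degenerate constant target: constants only stabilize
  c(c1 = (weights$ssim_k1 * r)^2, c2 = (weights$ssim_k2 * r)^2)
}

# ---- graph builders (shared by the numeric API and the trainer) ----------

ag_l1 <- function(tape, pred, target, mask = NULL) {
  d <- ag_abs(tape, ag_sub(tape, pred, ag_leaf(tape, target)))
  if (is.null(mask)) ag_mean(tape, d) else ag_masked_mean(tape, d, mask)
}

# Local SSIM map (valid window positions) built from differentiable
# primitives; constants are data-derived and treated as fixed.
ag_ssim_map <- function(tape, pred, target, k, c1, c2) {
  tn <- ag_leaf(tape, target)
  mx <- ag_winmean(tape, pred, k)
  my <- ag_winmean(tape, tn, k)
  mxx <- ag_winmean(tape, ag_mul(tape, pred, pred), k)
  myy <- ag_winmean(tape, ag_mul(tape, tn, tn), k)
  mxy <- ag_winmean(tape, ag_mul(tape, pred, tn), k)
  mx2 <- ag_mul(tape, mx, mx)
  my2 <- ag_mul(tape, my, my)
  vx <- ag_sub(tape, mxx, mx2)
  vy <- ag_sub(tape, myy, my2)
  cxy <- ag_sub(tape, mxy, ag_mul(tape, mx, my))
  num <- ag_mul(tape,
                ag_scale_shift(tape, ag_mul(tape, mx, my), 2, c1),
                ag_scale_shift(tape, cxy, 2, c2))
  den <- ag_mul(tape,
                ag_scale_shift(tape, ag_add(tape, mx2, my2), 1, c1),
                ag_scale_shift(tape, ag_add(tape, vx, vy), 1, c2))
  ag_div(tape, num, den)
}

# Crop a pixel mask to the window-centre positions of the valid SSIM map.
crop_mask <- function(mask, k) {
  d <- dim(mask)
  off <- (k - 1L) / 2L
  mask[off + seq_len(d[1] - k + 1L), off + seq_len(d[2] - k + 1L), , , drop = FALSE]
}

ag_ssim_loss <- function(tape, pred, target, weights, mask = NULL) {
  k <- weights$ssim_window
  d <- dim(pred$value)
  if (k > d[1] || k > d[2])
    stop("ssim window (", k, ") larger than image side (", min(d[1:2]), ")")
  cc <- ssim_constants(target, weights)
  map <- ag_ssim_map(tape, pred, target, k, cc["c1"], cc["c2"])
  one_minus <- ag_scale_shift(tape, map, -1, 1)
  if (is.null(mask)) ag_mean(tape, one_minus)
  else ag_masked_mean(tape, one_minus, crop_mask(mask, k))
}

ag_combined <- function(tape, pred, target, weights, mask = NULL) {
  l1 <- ag_l1(tape, pred, target, mask)
  ss <- ag_ssim_loss(tape, pred, target, weights, mask)
  list(loss = ag_add(tape, l1, ag_scale_shift(tape, ss, weights$alpha, 0)),
       l1 = l1, ssim = ss)
}

ag_lesion <- function(tape, pred, target, mask, weights) {
  whole <- ag_combined(tape, pred, target, weights)
  lesion <- ag_combined(tape, pred, target, weights, mask = mask)
  list(loss = ag_add(tape, whole$loss,
                     ag_scale_shift(tape, lesion$loss, weights$beta, 0)),
       whole = whole, lesion = lesion)
}

# ---- numeric (user-facing) API -------------------------------------------

run_scalar_loss <- function(pred, target, mask, builder, gradient = FALSE) {
  dim_in <- dim(pred)
  pred <- to4d(pred); target <- to4d(target)
  if (!is.null(mask)) mask <- to4d(mask)
  check_pair(pred, target, mask)
  tape <- new_tape()
  pn <- ag_leaf(tape, pred, requires_grad = gradient)
  node <- builder(tape, pn, target, mask)
  v <- as.numeric(node$value)
  if (!gradient) return(v)
  ag_backward(tape, node)
  g <- pn$grad
  dim(g) <- dim_in
  list(value = v, gradient = g)
}

#' Mean absolute (L1) loss
#'
#' Mean absolute difference over all pixels, or over mask-positive pixels
#' only when a binary mask is given. An all-zero mask yields 0 (with a note):
#' a lesion-free slice contributes no lesion term.
#'
#' @param pred,target matrices or arrays of equal shape.
#' @param mask optional binary mask of the same shape.
#' @return scalar loss.
#' @export
l1_loss <- function(pred, target, mask = NULL) {
  if (!is.null(mask) && sum(mask) == 0) {
    message("l1_loss: mask is empty; returning 0")
    return(0)
  }
  run_scalar_loss(pred, target, mask,
                  function(tape, p, t, m) ag_l1(tape, p, t, m))
}

#' Structural-similarity (SSIM) loss
#'
#' `1 - mean(local SSIM map)` over sliding windows (valid positions); in mask
#' mode the map is averaged over mask-positive window centres. The SSIM map
#' follows the standard luminance/contrast/structure form with constants
#' `(k1 R)^2`, `(k2 R)^2` from the target's dynamic range.
#'
#' @inheritParams l1_loss
#' @param weights a [loss_weights()] (window and constants).
#' @return scalar loss in `[0, 2]`.
#' @export
ssim_loss <- function(pred, target, mask = NULL, weights = loss_weights()) {
  run_scalar_loss(pred, target, mask,
                  function(tape, p, t, m) ag_ssim_loss(tape, p, t, weights, m))
}

#' Composite L1 + SSIM loss
#'
#' `L = L1 + alpha * L_ssim`.
#'
#' @inheritParams ssim_loss
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, weights = loss_weights()) {
  run_scalar_loss(pred, target, NULL,
                  function(tape, p, t, m) ag_combined(tape, p, t, weights)$loss)
}

#' Lesion-attention loss
#'
#' `l = L + beta * L_masked`, where `L` is the composite loss over the whole
#' image and `L_masked` the same composite recomputed over the lesion region
#' only (masked L1 and mask-averaged SSIM map).
#'
#' @inheritParams ssim_loss
#' @param mask binary lesion mask (required; may be all-zero).
#' @return scalar loss.
#' @export
lesion_attention_loss <- function(pred, target, mask, weights = loss_weights()) {
  run_scalar_loss(pred, target, mask,
                  function(tape, p, t, m) ag_lesion(tape, p, t, m, weights)$loss)
}

#' Deep-supervision total loss
#'
#' `L_total = sum_i w_side[i] * l_side[i] + w_final * l_final` over exactly
#' six side outputs plus the final output, each scored with the
#' lesion-attention loss.
#'
#' @param final final network output.
#' @param side_outputs list of exactly 6 side outputs.
#' @inheritParams lesion_attention_loss
#' @return scalar loss.
#' @export
total_loss <- function(final, side_outputs, target, mask,
                       weights = loss_weights()) {
  if (length(side_outputs) != 6L)
    stop("expected exactly 6 side outputs, got ", length(side_outputs))
  acc <- weights$w_final * lesion_attention_loss(final, target, mask, weights)
  for (i in 1:6)
    acc <- acc + weights$w_side[i] *
      lesion_attention_loss(side_outputs[[i]], target, mask, weights)
  acc
}

#' Loss value and analytic gradient with respect to the prediction
#'
#' Convenience wrapper exposing the reverse-mode gradient of each loss, e.g.
#' for optimizer diagnostics or finite-difference verification.
#'
#' @inheritParams ssim_loss
#' @param type which loss to differentiate.
#' @param mask binary mask (required for `"lesion"`).
#' @return list with `value` and `gradient` (same shape as `pred`).
#' @export
loss_with_gradient <- function(pred, target, mask = NULL,
                               weights = loss_weights(),
                               type = c("combined", "lesion", "l1", "ssim")) {
  type <- match.arg(type)
  builder <- switch(type,
    l1 = function(tape, p, t, m) ag_l1(tape, p, t, m),
    ssim = function(tape, p, t, m) ag_ssim_loss(tape, p, t, weights, m),
    combined = function(tape, p, t, m) ag_combined(tape, p, t, weights)$loss,
    lesion = function(tape, p, t, m) {
      if (is.null(m)) stop("lesion loss needs a mask")
      ag_lesion(tape, p, t, m, weights)$loss
    })
  run_scalar_loss(pred, target, mask, builder, gradient = TRUE)
}
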