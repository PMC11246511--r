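# Training objectives: soft Dice, distance-transform Hausdorff, focal, and
# least-squares adversarial losses, combined into one weighted objective.
# Each loss has an analytic gradient with respect to the prediction; the
# distance-transform weights are treated as constants within a step.

#' Integrated loss weights
#'
#' Weights of the four terms of the training objective:
#' `lambda * Dice + alpha_w * Hausdorff + beta * Focal + gamma_adv * LSGAN`.
#'
#' @param lambda Dice weight, default 10.
#' @param alpha_w Hausdorff weight, default 1e-4.
#' @param beta Focal weight, default 10.
#' @param gamma_adv Adversarial weight, default 0.1.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda = 10, alpha_w = 1e-4, beta = 10,
                         gamma_adv = 0.1) {
  w <- c(lambda = lambda, alpha_w = alpha_w, beta = beta,
         gamma_adv = gamma_adv)
  if (any(w < 0)) stopf("loss weights must be >= 0")
  structure(as.list(w), class = "loss_weights")
}

#' Focal loss parameters
#'
#' @param alpha_t Foreground weighting factor in (0, 1), default 0.2 (the
#'   background receives `1 - alpha_t`).
#' @param gamma_f Focusing exponent, default 5.
#' @return An object of class `focal_params`.
#' @export
focal_params <- function(alpha_t = 0.2, gamma_f = 5) {
  if (alpha_t <= 0 || alpha_t >= 1) stopf("alpha_t must lie in (0, 1)")
  if (gamma_f < 0) stopf("gamma_f must be >= 0")
  structure(list(alpha_t = alpha_t, gamma_f = gamma_f),
            class = "focal_params")
}

#' Distance-transform Hausdorff loss parameters
#'
#' @param dt_power Exponent applied to the two distance transforms, default
#'   2 (following the distance-transform Hausdorff-loss literature).
#' @return An object of class `hausdorff_params`.
#' @export
hausdorff_params <- function(dt_power = 2) {
  if (dt_power <= 0) stopf("dt_power must be positive")
  structure(list(dt_power = dt_power), class = "hausdorff_params")
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(pred * mask) / (sum(pred) + sum(mask) + eps)`.
#'
#' @param pred Numeric array of probabilities in `[0, 1]`.
#' @param mask Binary array of the same shape.
#' @param eps Smoothing constant, default 1e-6.
#' @return Scalar loss in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(pred, mask, eps = 1e-6) {
  stopifnot(length(pred) == length(mask))
  1 - 2 * sum(pred * mask) / (sum(pred) + sum(mask) + eps)
}

# d(dice_loss)/d(pred), elementwise.
dice_loss_grad <- function(pred, mask, eps = 1e-6) {
  den <- sum(pred) + sum(mask) + eps
  num <- 2 * sum(pred * mask)
  array(-(2 * mask * den - num) / den^2, dim = dim(pred))
}

# Distance (in voxels/mm) from every voxel to the boundary of `mask`; the
# boundary is the set of foreground voxels with a background 6-neighbour
# (volume border counting as background).  Masks without a boundary (empty
# or full) yield zero distances, so the weight falls back on the other term.
boundary_dt <- function(mask, spacing = c(1, 1, 1)) {
  surf <- surface_logical(mask)
  if (!any(surf)) return(array(0, dim = dim(mask)))
  cpp_edt3d(surf, as.numeric(spacing))
}

#' Distance-transform Hausdorff loss
#'
#' Mean over the voxel domain of `(p - q)^2 * (d_p^a + d_q^a)` where `d_q`
#' is the Euclidean distance transform to the ground-truth boundary and
#' `d_p` the distance transform to the boundary of the prediction
#' thresholded at 0.5.  Both transforms are treated as constants (no
#' gradient flows through them).
#'
#' @param pred Probability array.
#' @param mask Binary array of the same shape.
#' @param params A [hausdorff_params()].
#' @param spacing Voxel spacing used by the distance transforms.
#' @return Scalar loss >= 0.
#' @export
hausdorff_dt_loss <- function(pred, mask, params = hausdorff_params(),
                              spacing = c(1, 1, 1)) {
  stopifnot(identical(dim(pred), dim(mask)))
  w <- hausdorff_dt_weight(pred, mask, params, spacing)
  mean((pred - mask)^2 * w)
}

hausdorff_dt_weight <- function(pred, mask, params = hausdorff_params(),
                                spacing = c(1, 1, 1)) {
  dq <- boundary_dt(mask >= 0.5, spacing)
  dp <- boundary_dt(pred >= 0.5, spacing)
  dp^params$dt_power + dq^params$dt_power
}

# Gradient given precomputed constant weights w.
hausdorff_dt_loss_grad <- function(pred, mask, w) {
  2 * (pred - mask) * w / length(pred)
}

#' Focal loss
#'
#' Mean over voxels of `-w * (1 - p_t)^gamma_f * log(p_t)` with
#' `p_t = pred` on foreground and `1 - pred` on background; `w = alpha_t`
#' on foreground and `1 - alpha_t` on background.  Predictions are clamped
#' to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred Probability array.
#' @param mask Binary array of the same shape.
#' @param params A [focal_params()].
#' @return Scalar loss >= 0.
#' @export
focal_loss <- function(pred, mask, params = focal_params()) {
  stopifnot(length(pred) == length(mask))
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  pt <- ifelse(mask >= 0.5, p, 1 - p)
  w <- ifelse(mask >= 0.5, params$alpha_t, 1 - params$alpha_t)
  mean(-w * (1 - pt)^params$gamma_f * log(pt))
}

# d(focal_loss)/d(pred), elementwise (zero where clamped).
focal_loss_grad <- function(pred, mask, params = focal_params()) {
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  fg <- mask >= 0.5
  pt <- ifelse(fg, p, 1 - p)
  w <- ifelse(fg, params$alpha_t, 1 - params$alpha_t)
  g <- params$gamma_f
  # dL/dpt per voxel, then dpt/dpred = +1 (fg) or -1 (bg)
  dpt <- -w * (-g * (1 - pt)^(g - 1) * log(pt) + (1 - pt)^g / pt)
  dpt <- dpt * ifelse(fg, 1, -1)
  dpt[pred < eps | pred > 1 - eps] <- 0
  array(dpt / length(pred), dim = dim(pred))
}

#' Least-squares adversarial losses
#'
#' Generator loss `mean((D(G(x)) - 1)^2)`; discriminator loss
#' `mean((D(y) - 1)^2) + mean((D(G(x)) - 0)^2)`.
#'
#' @param d_on_fake Discriminator score map on generated volumes.
#' @param d_on_real Discriminator score map on real masks.
#' @return List with `g_loss` and `d_loss`.
#' @export
lsgan_losses <- function(d_on_fake, d_on_real) {
  if (any(!is.finite(d_on_fake)) || any(!is.finite(d_on_real)))
    stopf("score maps must be finite")
  list(g_loss = mean((d_on_fake - 1)^2),
       d_loss = mean((d_on_real - 1)^2) + mean(d_on_fake^2))
}

#' Integrated training loss
#'
#' Weighted sum `lambda * dice + alpha_w * hausdorff + beta * focal +
#' gamma_adv * adv_g`.
#'
#' @param dice,hausdorff,focal,adv_g Scalar loss components.
#' @param weights A [loss_weights()].
#' @return Scalar total loss.
#' @export
integrated_loss <- function(dice, hausdorff, focal, adv_g,
                            weights = loss_weights()) {
  comps <- c(dice, hausdorff, focal, adv_g)
  if (any(!is.finite(comps))) stopf("loss components must be finite")
  weights$lambda * dice + weights$alpha_w * hausdorff +
    weights$beta * focal + weights$gamma_adv * adv_g
}
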