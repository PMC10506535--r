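# Loss functions of the virtual-staining (G1) and cycle (G2/G3) objectives.
#
# The staining generator minimises adversarial + alpha * pixel MSE +
# gamma * perceptual terms (alpha = 0.01, gamma = 0.005 by default); the
# unpaired FF-to-FFPE translator minimises both directions' adversarial
# terms plus lambda * (both cycle reconstruction L1 terms) with lambda = 10.
# The adversarial form is the least-squares GAN objective; it is isolated
# in loss_adversarial so the functional form is a single-point change.

#' Loss weights
#'
#' @param alpha Weight on the pixel MSE term (default 0.01).
#' @param gamma Weight on the perceptual term (default 0.005).
#' @param lambda_cyc Weight on the cycle-consistency term (default 10).
#' @return A `loss_weights` list; negative weights are an error.
#' @export
loss_weights <- function(alpha = 0.01, gamma = 0.005, lambda_cyc = 10) {
  if (alpha < 0 || gamma < 0 || lambda_cyc < 0) {
    stop("loss weights must be nonnegative")
  }
  structure(list(alpha = alpha, gamma = gamma, lambda_cyc = lambda_cyc),
            class = "loss_weights")
}

#' Mean squared error
#'
#' @param pred,target Arrays of identical shape.
#' @return Scalar mean of squared elementwise differences.
#' @export
loss_mse <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target))) {
    stop("shape mismatch in loss_mse")
  }
  mean((pred - target)^2)
}

# d/dpred of loss_mse
grad_mse <- function(pred, target) 2 * (pred - target) / length(pred)

#' Perceptual loss under a fixed feature extractor
#'
#' Mean over the extractor's named taps of the MSE between the feature maps
#' of `pred` and `target`. With the identity extractor this equals
#' [loss_mse()] exactly.
#'
#' @param pred,target Arrays of identical shape.
#' @param fx A [feature_extractor()].
#' @return Nonnegative scalar.
#' @export
loss_perceptual <- function(pred, target, fx) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  fp <- fx_forward(fx, pred)$taps
  ft <- fx_forward(fx, target)$taps
  mean(vapply(names(fp), function(nm) loss_mse(fp[[nm]], ft[[nm]]),
              numeric(1)))
}

# Gradient of loss_perceptual w.r.t. pred (target held fixed).
grad_perceptual <- function(pred, target, fx) {
  fp <- fx_forward(fx, pred)
  ft <- fx_forward(fx, target)$taps
  k <- length(fp$taps)
  dtaps <- lapply(names(fp$taps), function(nm) {
    grad_mse(fp$taps[[nm]], ft[[nm]]) / k
  })
  names(dtaps) <- names(fp$taps)
  fx_backward(fx, fp$cache, dtaps)
}

#' Least-squares adversarial loss
#'
#' Mean over discriminator scales of the mean squared deviation of the
#' score maps from `target_label` (1 = "call it real", 0 = "call it fake").
#'
#' @param d_scores List of per-scale score maps.
#' @param target_label 0 or 1.
#' @return Nonnegative scalar.
#' @export
loss_adversarial <- function(d_scores, target_label) {
  mean(vapply(d_scores, function(s) mean((s - target_label)^2), numeric(1)))
}

# Per-scale gradients of loss_adversarial w.r.t. the scores.
grad_adversarial <- function(d_scores, target_label) {
  k <- length(d_scores)
  lapply(d_scores, function(s) 2 * (s - target_label) / (length(s) * k))
}

#' Full staining-generator objective
#'
#' total = adversarial(d_scores, 1) + alpha * MSE(pred, target) +
#' gamma * perceptual(pred, target). Returns the total and the three terms.
#'
#' @param pred Generator output.
#' @param target Ground-truth H&E patch.
#' @param d_scores Discriminator score maps for `pred`.
#' @param fx A [feature_extractor()].
#' @param weights A [loss_weights()].
#' @return List `total`, `adversarial`, `mse`, `perceptual` (unweighted
#'   terms; the total applies the weights).
#' @export
g1_total_loss <- function(pred, target, d_scores, fx,
                          weights = loss_weights()) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, weights)
  adv <- loss_adversarial(d_scores, 1)
  mse <- loss_mse(pred, target)
  perc <- loss_perceptual(pred, target, fx)
  list(total = adv + weights$alpha * mse + weights$gamma * perc,
       adversarial = adv, mse = mse, perceptual = perc)
}

#' Cycle-consistency loss
#'
#' Mean absolute (L1) difference between an image and its round-trip
#' reconstruction through both translators.
#'
#' @param x Original image.
#' @param reconstruction Round-trip output, same shape.
#' @return Nonnegative scalar; 0 iff the round trip is exact.
#' @export
loss_cycle <- function(x, reconstruction) {
  if (!identical(dim(x) %||% length(x),
                 dim(reconstruction) %||% length(reconstruction))) {
    stop("shape mismatch in loss_cycle")
  }
  mean(abs(x - reconstruction))
}

# d/drecon of loss_cycle (subgradient sign convention at 0).
grad_cycle <- function(x, reconstruction) {
  sign(reconstruction - x) / length(x)
}

#' Full cycle-GAN objective
#'
#' Sum of both directions' generator adversarial terms plus
#' `lambda_cyc` times the sum of both cycle terms.
#'
#' @param adv_terms Numeric vector: adversarial losses for the FF-to-FFPE
#'   and FFPE-to-FF generators.
#' @param cycle_terms Numeric vector: both cycle reconstruction losses.
#' @param weights A [loss_weights()].
#' @return List `total`, `adversarial`, `cycle`.
#' @export
cycle_total_loss <- function(adv_terms, cycle_terms,
                             weights = loss_weights()) {
  list(total = sum(adv_terms) + weights$lambda_cyc * sum(cycle_terms),
       adversarial = sum(adv_terms), cycle = sum(cycle_terms))
}
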