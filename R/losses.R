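# Training losses of the virtual-staining cGAN, as pure functions.
#
# The adversarial system has three loss surfaces:
#   generator:      alpha * L1s(target, warp(G(x, c), R(...)))
#                 + beta  * BCE(D(G(x, c), c), 1) + gamma * TV(G(x, c))
#   discriminator:  BCE(D(fake), 0) + BCE(D(real), 1)
#   registration:   lambda * L1s(target, warp(G_out, field)) + mu * SMTH(field)
# with default coefficients (10, 1, 1e-4) and (20, 10), smooth-L1 knee
# phi = 1.  TV is the anisotropic, un-normalized sum of absolute forward
# differences; SMTH is the mean squared forward difference of the field.

#' Default loss weights
#'
#' Coefficients of the three training objectives: `alpha`, `beta`, `gamma`
#' weight the smooth-L1, adversarial BCE and total-variation terms of the
#' generator loss; `lam` and `mu` weight the smooth-L1 and field-smoothness
#' terms of the registration loss; `phi` is the smooth-L1 knee.
#'
#' @param alpha,beta,gamma Generator loss coefficients (default 10, 1, 1e-4).
#' @param lam,mu Registration loss coefficients (default 20, 10).
#' @param phi Smooth-L1 transition point (default 1).
#' @return A named list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 10, beta = 1, gamma = 1e-4,
                         lam = 20, mu = 10, phi = 1) {
  w <- list(alpha = alpha, beta = beta, gamma = gamma,
            lam = lam, mu = mu, phi = phi)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

#' Smooth L1 loss
#'
#' Mean over all elements of the Huber-style penalty: `0.5 d^2 / phi` where
#' `|d| < phi`, and `|d| - 0.5 phi` otherwise, with `d = A - B`.  Both
#' branches agree at `|d| = phi`.  Multi-channel inputs are averaged over
#' channels as well as pixels.
#'
#' @param A,B Numeric arrays of identical shape.
#' @param phi Transition point between the quadratic and linear branch.
#' @return Scalar loss.
#' @export
smooth_l1 <- function(A, B, phi = 1) {
  if (!identical(dim(A) %||% length(A), dim(B) %||% length(B)))
    stop("smooth_l1: shape mismatch")
  if (phi <= 0) stop("smooth_l1: phi must be positive")
  d <- A - B
  mean(ifelse(abs(d) < phi, 0.5 * d^2 / phi, abs(d) - 0.5 * phi))
}

#' Binary cross-entropy
#'
#' `-(label * log(p) + (1 - label) * log(1 - p))` with the prediction
#' clamped to `[eps, 1 - eps]` so the loss stays finite at saturated
#' predictions.
#'
#' @param p_pred Predicted probability (scalar or vector) in `[0, 1]`.
#' @param label True label, 0 or 1.
#' @param eps Clamp width (default 1e-7).
#' @return Scalar loss (mean over elements).
#' @export
bce <- function(p_pred, label, eps = 1e-7) {
  p <- pmin(pmax(p_pred, eps), 1 - eps)
  mean(-(label * log(p) + (1 - label) * log(1 - p)))
}

#' Anisotropic total variation
#'
#' Un-normalized sum of absolute forward differences along rows and columns,
#' summed over channels; differences run to the last valid index (no
#' wraparound or padding).  Acts as the generator's spatial regularizer.
#'
#' @param I Matrix or (H, W, C) array.
#' @return Scalar.
#' @export
total_variation <- function(I) {
  I <- as_image3(I)
  d <- dim(I)
  sum(abs(I[-1, , , drop = FALSE] - I[-d[1], , , drop = FALSE])) +
    sum(abs(I[, -1, , drop = FALSE] - I[, -d[2], , drop = FALSE]))
}

#' Displacement-field smoothness penalty
#'
#' Mean (over the `X x Y` grid) of squared forward differences of the field,
#' summed over the two displacement components.
#'
#' @param T_field (H, W, 2) displacement field (dx, dy in pixels).
#' @return Scalar.
#' @export
smoothness <- function(T_field) {
  f <- as_image3(T_field)
  d <- dim(f)
  N <- d[1] * d[2]
  (sum((f[-1, , , drop = FALSE] - f[-d[1], , , drop = FALSE])^2) +
     sum((f[, -1, , drop = FALSE] - f[, -d[2], , drop = FALSE])^2)) / N
}

#' Generator loss
#'
#' Builds the full differentiable generator objective for one sample on a
#' fresh tape and returns its value and components.  The registration module
#' `reg` may be `NULL`, in which case the warp is the identity (used for
#' perfectly aligned data and for style-transfer training during data
#' preparation).
#'
#' @param input (H, W, Cin) autofluorescence stack.
#' @param dsm Digital staining matrix (H, W) from [make_dsm()].
#' @param target (H, W, 3) registered ground-truth stained image.
#' @param gen,disc,reg Networks from [build_generator()],
#'   [build_discriminator()], [build_registration_module()].
#' @param weights [loss_weights()].
#' @return List with `total`, `l1`, `adv`, `tv` (scalar values).
#' @export
generator_loss <- function(input, dsm, target, gen, disc, reg = NULL,
                           weights = loss_weights()) {
  g <- gan_graph(input, dsm, target, gen, disc, reg, weights,
                 need = "generator")
  g$components
}

#' Discriminator loss
#'
#' `BCE(fake, 0) + BCE(real, 1)` on the discriminator's scalar predictions.
#'
#' @param fake_pred,real_pred Predicted probabilities in `[0, 1]`.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(fake_pred, real_pred) {
  bce(fake_pred, 0) + bce(real_pred, 1)
}

#' Registration-module loss
#'
#' `lam * smooth_l1(target, warp(G_out, field)) + mu * smoothness(field)`
#' where `field = R(G_out, target)`.
#'
#' @param target (H, W, 3) fixed image.
#' @param G_out (H, W, 3) moving image (generator output).
#' @param reg Registration network.
#' @param weights [loss_weights()].
#' @return List with `total`, `l1`, `smth` and the predicted `field`.
#' @export
registration_loss <- function(target, G_out, reg, weights = loss_weights()) {
  tape <- new_tape()
  ps <- wrap_params(tape, reg$params)
  fn <- registration_forward_graph(tape, ps, reg$config,
                                   nd_const(tape, as_image3(G_out)),
                                   nd_const(tape, as_image3(target)))
  warped <- nd_grid_sample(tape, nd_const(tape, as_image3(G_out)), fn)
  l1 <- nd_smooth_l1(tape, warped, nd_const(tape, as_image3(target)),
                     weights$phi)
  sm <- nd_smoothness(tape, fn)
  list(total = weights$lam * l1$value + weights$mu * sm$value,
       l1 = l1$value, smth = sm$value, field = fn$value)
}
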