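# Adversarial feature-subspace perturbation: a one-step gradient
# construction in embedding space. A random probe r on the epsilon-sphere is
# applied to the second predictor slot; the gradient of the prediction
# discrepancy D(N(f,f), N(f,f+r)) with respect to r, rescaled to length eta,
# is the perturbation d used both to stabilize the predictor and as the cue
# for single-atom optimization.

#' Sample a random probe on the epsilon-sphere
#'
#' Draws a standard Gaussian vector and rescales it to l2 norm `epsilon`
#' exactly, giving a deterministic probe length for a given seed.
#'
#' @param dim Embedding dimension.
#' @param epsilon Probe radius (> 0).
#' @return Numeric vector of length `dim` with `sqrt(sum(r^2)) == epsilon`.
#' @export
sample_probe <- function(dim, epsilon) {
  stopifnot(epsilon > 0, dim >= 1)
  r <- stats::rnorm(dim)
  nr <- sqrt(sum(r^2))
  if (nr < 1e-300) r <- rep(1 / sqrt(dim), dim) else r <- r / nr
  r * epsilon
}

# prediction discrepancy D(x, y): squared difference of predictor outputs
.divergence <- function(x, y) (x - y)^2

#' Adversarial perturbation of a molecular embedding
#'
#' Computes `g`, the gradient with respect to the probe `r` of the squared
#' prediction discrepancy `D(N(f,f), N(f,f+r))`, evaluated at a random probe
#' of norm `epsilon`, and returns `d = eta * g / ||g||`. When the probe
#' lands on a flat spot (`||g|| < 1e-12`) the zero vector is returned with
#' `flat = TRUE`.
#'
#' Note that `d` points along the gradient of a *symmetric* discrepancy, so
#' its sign is not tied to increasing activity; see [orient_perturbation()]
#' for the direction convention used by the optimization pipeline.
#'
#' @param model A `cliffopt_model`.
#' @param f Molecular embedding (numeric vector).
#' @param eta Perturbation norm; defaults to the model configuration.
#' @param epsilon Probe radius; defaults to the model configuration.
#' @return A list with `d` (numeric vector, `||d|| = eta` unless flat),
#'   `g` (raw gradient), `probe`, `eta`, `epsilon`, `flat`.
#' @export
adversarial_perturbation <- function(model, f,
                                     eta = model$config$eta,
                                     epsilon = model$config$epsilon) {
  d_out <- .afse_batch(model$params, model$config, matrix(f, nrow = 1),
                       eta = eta, epsilon = epsilon)
  list(d = as.vector(d_out$d), g = as.vector(d_out$g),
       probe = as.vector(d_out$probe), eta = eta, epsilon = epsilon,
       flat = d_out$flat[1])
}

# batched version: one probe and one perturbation per row of f_mat
.afse_batch <- function(params, cfg, f_mat, eta = cfg$eta,
                        epsilon = cfg$epsilon) {
  n <- nrow(f_mat); ddim <- ncol(f_mat)
  probes <- t(vapply(seq_len(n), function(i) sample_probe(ddim, epsilon),
                     numeric(ddim)))
  tp <- ad_tape()
  P <- .param_binder(tp, params)
  fc <- ad_const(tp, f_mat)
  r <- ad_leaf(tp, probes, "__r__")
  pred0 <- pred_forward(tp, P, fc, fc)
  predr <- pred_forward(tp, P, fc, ad_add(tp, fc, r))
  e <- ad_sub(tp, pred0, predr)
  loss <- ad_sum(tp, ad_mul(tp, e, e))
  g <- ad_backward(tp, loss)$`__r__`
  if (any(!is.finite(g))) stop("gradient overflow in adversarial perturbation")
  norms <- sqrt(rowSums(g^2))
  flat <- norms < 1e-12
  scale <- ifelse(flat, 0, eta / pmax(norms, 1e-300))
  list(d = g * scale, g = g, probe = probes, flat = flat)
}

#' Orient a perturbation toward higher predicted activity
#'
#' The adversarial construction fixes only the line of `d`, not its sign.
#' The optimization pipeline adopts the convention that the forward
#' direction increases the predicted activity: this helper returns `+1`
#' when `N(f, f+d) >= N(f, f)` and `-1` otherwise, and the pipeline uses
#' `sign * d` as the forward perturbation.
#'
#' @param model A `cliffopt_model`.
#' @param f Molecular embedding.
#' @param d Perturbation vector.
#' @return `+1` or `-1`.
#' @export
orient_perturbation <- function(model, f, d) {
  delta <- predict_pair(model, f, f + d) - predict_pair(model, f, f)
  if (delta >= 0) 1 else -1
}

#' Adversarial stabilization loss
#'
#' The squared prediction discrepancy `D(N(f,f), N(f,f+d))` for a fixed
#' perturbation `d`. Zero exactly when the predictions agree; minimized
#' during training to make the predictor locally smooth around each
#' molecule, which is what tempers activity-cliff errors.
#'
#' @param model A `cliffopt_model`.
#' @param f Molecular embedding.
#' @param d Perturbation (treated as a constant).
#' @return Nonnegative scalar.
#' @export
afse_loss <- function(model, f, d) {
  .divergence(predict_pair(model, f, f), predict_pair(model, f, f + d))
}
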