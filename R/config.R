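#' Model and training configuration
#'
#' Collects every tunable of the method in one list. Defaults follow the
#' published settings where the method states them (`T = 1` molecule-to-atom
#' steps, `L = 2` message-passing layers, balance coefficients
#' `lambda1 = 0.6`, `lambda2 = 0.3`) and otherwise use desk-scale values
#' documented in the methods vignette.
#'
#' @param hidden_dim Embedding width `D_h` of atomic and molecular
#'   embeddings (default 64).
#' @param n_layers `L`, number of message-passing layers in the encoder and
#'   refinement layers in the decoder.
#' @param t_steps `T`, number of molecule-to-atom GRU refinement steps in
#'   the decoder.
#' @param eta Perturbation magnitude: the adversarial vector `d` is scaled
#'   to this l2 norm. The main user knob for how far in embedding space the
#'   optimization probes; it must be comparable to the embedding
#'   displacement of a single-atom edit for the decoder to cross between
#'   pair embeddings (see the methods vignette for the scale argument).
#' @param epsilon Radius of the random Gaussian probe used to estimate the
#'   adversarial direction.
#' @param p0 Posterior confidence threshold used both for the confusable
#'   set (reconstruction side) and the candidate set (optimization side).
#' @param lambda1,lambda2 Balance coefficients of the adversarial
#'   stabilization loss and of the reconstruction + validity losses.
#' @param dropout Dropout rate, active in training mode only.
#' @param include_bonds Reconstruct bond features as well as atom symbols
#'   (off by default; atom symbols are what the optimization edits).
#' @param task `"regression"` (activity on the pActivity scale) or
#'   `"classification"` (0/1 labels, logit output).
#' @param epochs,batch_size,base_lr Training loop controls.
#' @param warmup_frac Fraction of total steps used for the linear
#'   learning-rate warm-up; the rate then decays linearly to zero.
#' @param val_frac Fraction of the training set held out for the per-epoch
#'   validation metric.
#' @param seed Integer seed governing all randomness (initialization,
#'   probes, dropout, batch order).
#' @return A list of class `cliffopt_config`.
#' @export
cliffopt_config <- function(hidden_dim = 64,
                            n_layers = 2,
                            t_steps = 1,
                            eta = 5.0,
                            epsilon = 0.01,
                            p0 = 0.5,
                            lambda1 = 0.6,
                            lambda2 = 0.3,
                            dropout = 0.1,
                            include_bonds = FALSE,
                            task = c("regression", "classification"),
                            epochs = 100,
                            batch_size = 32,
                            base_lr = 5e-3,
                            warmup_frac = 0.1,
                            val_frac = 0.1,
                            seed = 1L) {
  task <- match.arg(task)
  stopifnot(hidden_dim >= 1, n_layers >= 1, t_steps >= 1,
            eta > 0, epsilon > 0, p0 > 0, p0 < 1,
            lambda1 >= 0, lambda2 >= 0, dropout >= 0, dropout < 1)
  structure(
    list(hidden_dim = as.integer(hidden_dim), n_layers = as.integer(n_layers),
         t_steps = as.integer(t_steps), eta = eta, epsilon = epsilon, p0 = p0,
         lambda1 = lambda1, lambda2 = lambda2, dropout = dropout,
         include_bonds = isTRUE(include_bonds), task = task,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         base_lr = base_lr, warmup_frac = warmup_frac, val_frac = val_frac,
         seed = as.integer(seed)),
    class = "cliffopt_config"
  )
}

#' @export
print.cliffopt_config <- function(x, ...) {
  cat("<cliffopt_config>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
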