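# User-facing encoder and predictor surface. The heavy lifting lives in
# nn-core.R; functions here run the batched forward passes in evaluation
# mode (dropout off) and return plain numeric results.

.encode_batch <- function(params, cfg, graphs, feats = NULL) {
  batch <- build_batch(graphs, feats)
  tp <- ad_tape()
  P <- .param_binder(tp, params)
  e <- enc_forward(tp, P, batch, cfg, drop = NULL)
  list(batch = batch, tp = tp, P = P, H_id = e$H, f_id = e$f,
       H = ad_val(tp, e$H), f = ad_val(tp, e$f))
}

#' Encode a molecule into atomic and molecular embeddings
#'
#' Runs the attentive message-passing encoder in evaluation mode. The
#' molecular embedding is the sum of the atomic embeddings (sum readout), so
#' `f == colSums(H)` exactly and `f` is invariant to atom relabeling.
#'
#' @param model A fitted `cliffopt_model` (or any list with `params` and
#'   `config`).
#' @param g A `mol_graph`.
#' @return A list with `f` (numeric vector of length `hidden_dim`) and `H`
#'   (`N_a x hidden_dim` matrix of atomic embeddings).
#' @export
encode <- function(model, g) {
  stopifnot(inherits(g, "mol_graph"))
  e <- .encode_batch(model$params, model$config, list(g))
  list(f = as.vector(e$f), H = e$H)
}

#' Two-slot bioactivity predictor
#'
#' Evaluates the feed-forward predictor `N(f1, f2)` on a pair of molecular
#' embeddings. During training the first slot always carries the clean
#' embedding; the second slot carries either the clean or the perturbed one.
#'
#' @param model A `cliffopt_model`.
#' @param f1,f2 Numeric vectors of length `hidden_dim`.
#' @return A single numeric value (pActivity for regression, a logit for
#'   classification).
#' @export
predict_pair <- function(model, f1, f2) {
  stopifnot(length(f1) == length(f2))
  tp <- ad_tape()
  P <- .param_binder(tp, model$params)
  out <- pred_forward(tp, P, ad_const(tp, matrix(f1, 1)),
                      ad_const(tp, matrix(f2, 1)))
  as.numeric(ad_val(tp, out))
}

# batched N(f, f + delta); f_mat and delta are plain matrices
.predict_mat <- function(params, f_mat, delta = NULL) {
  tp <- ad_tape()
  P <- .param_binder(tp, params)
  f1 <- ad_const(tp, f_mat)
  f2 <- if (is.null(delta)) f1 else ad_const(tp, f_mat + delta)
  as.vector(ad_val(tp, pred_forward(tp, P, f1, f2)))
}

#' Predict bioactivity for a molecule table
#'
#' @param object A fitted `cliffopt_model`.
#' @param newdata A data frame with a `smiles` column, or a list of
#'   `mol_graph` objects.
#' @param ... Unused.
#' @return The input as a tibble with an added `.pred` column (predicted
#'   pActivity, or predicted probability for classification together with
#'   `.logit`).
#' @export
predict.cliffopt_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    graphs <- parse_smiles(newdata$smiles)
    if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
    out <- tibble::as_tibble(newdata)
  } else {
    graphs <- newdata
    out <- tibble::tibble(smiles = to_canonical_smiles(graphs))
  }
  preds <- numeric(length(graphs))
  for (chunk in split(seq_along(graphs), ceiling(seq_along(graphs) / 64))) {
    e <- .encode_batch(object$params, object$config, graphs[chunk])
    preds[chunk] <- .predict_mat(object$params, e$f)
  }
  if (object$config$task == "classification") {
    out$.logit <- preds
    out$.pred <- stats::plogis(preds)
  } else {
    out$.pred <- preds
  }
  out
}
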