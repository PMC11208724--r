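# The attentive graph reconstruction decoder: decompose a (possibly
# perturbed) molecular embedding onto atoms, refine atom and edge states
# with GRU/attention stages, and emit per-atom symbol probabilities (and,
# optionally, bond features). Exposed both as individual stages — useful
# for inspection and testing — and as the composite decode().

#' Decompose a molecular embedding onto atoms
#'
#' The atomic responsibility for a (possibly perturbed) molecular embedding:
#' a softmax over atoms of the inner products between `f_in` and the atomic
#' embeddings, so atoms whose embedding aligns with the perturbed molecular
#' embedding receive more of it.
#'
#' @param f_in Molecular embedding, possibly perturbed (`f + s*d`).
#' @param H `N_a x hidden_dim` matrix of atomic embeddings.
#' @return Numeric vector `gamma` on the simplex (positive, sums to 1).
#' @examples
#' decompose(c(1, 0), rbind(c(0, 0), c(log(2), 0), c(log(4), 0)))  # 1/7 2/7 4/7
#' @export
decompose <- function(f_in, H) {
  stopifnot(length(f_in) == ncol(H), nrow(H) >= 1)
  s <- as.vector(H %*% f_in)
  e <- exp(s - max(s))
  e / sum(e)
}

#' Molecule-to-atom update
#'
#' Starts each atom at `g_i = gamma_i * f_in + h_i` and refines it with
#' `t_steps` rounds of a relationship layer (elu-activated linear map of
#' `[f_in, g_i]`) followed by a GRU update with relu output.
#'
#' @param model A `cliffopt_model`.
#' @param f_in Molecular embedding (possibly perturbed).
#' @param H Atomic embedding matrix.
#' @param gamma Optional decomposition weights; computed by [decompose()]
#'   when omitted.
#' @param t_steps Number of refinement rounds; defaults to the model
#'   configuration.
#' @return List with `gT` (the initial states, before any GRU step) and
#'   `g0` (`N_a x hidden_dim`, after the final step; elementwise >= 0).
#' @export
molecule_to_atom <- function(model, f_in, H, gamma = NULL, t_steps = NULL) {
  cfg <- model$config
  if (is.null(t_steps)) t_steps <- cfg$t_steps
  if (is.null(gamma)) gamma <- decompose(f_in, H)
  n <- nrow(H)
  tp <- ad_tape()
  P <- .param_binder(tp, model$params)
  fin_atoms <- ad_const(tp, matrix(f_in, n, length(f_in), byrow = TRUE))
  g <- ad_add(tp, ad_colscale(tp, fin_atoms, ad_const(tp, matrix(gamma, ncol = 1))),
              ad_const(tp, H))
  gT <- ad_val(tp, g)
  for (t in seq_len(t_steps)) {
    r <- ad_elu(tp, ad_add_bias(tp,
          ad_matmul(tp, ad_cbind(tp, fin_atoms, g), P("dec.rel.W")),
          P("dec.rel.b")))
    g <- ad_relu(tp, .ad_gru_step(tp, P, "dec.gru1", r, g))
  }
  list(gT = gT, g0 = ad_val(tp, g))
}

#' Atom-to-atom update
#'
#' Refines atom states by attending over each atom's bonded neighbors for
#' `n_layers` rounds, maintaining directed edge states alongside. For a
#' single-atom molecule there is no neighborhood to attend over and the
#' aggregated context is the zero vector.
#'
#' @param model A `cliffopt_model`.
#' @param g0 `N_a x hidden_dim` matrix of atom states (from
#'   [molecule_to_atom()]).
#' @param g A `mol_graph` providing the bond structure.
#' @return List with `g_atoms` (final atom states), `g_edges` (final
#'   directed-edge states, or NULL), `edges` (tibble `src`, `dst`) and
#'   `attention` (list, per layer, of the attention weight vector aligned
#'   with `edges`; each receiver's weights sum to 1).
#' @export
atom_to_atom <- function(model, g0, g) {
  cfg <- model$config
  batch <- build_batch(list(g))
  tp <- ad_tape()
  P <- .param_binder(tp, model$params)
  st <- .dec_atom_stage(tp, P, batch, ad_const(tp, g0), cfg, drop = NULL)
  list(
    g_atoms = ad_val(tp, st$g),
    g_edges = if (!is.null(st$ge)) ad_val(tp, st$ge) else NULL,
    edges = tibble::tibble(src = batch$src, dst = batch$dst),
    attention = lapply(st$att_ids, function(id) as.vector(ad_val(tp, id)))
  )
}

# shared atom-to-atom stage used by both the API above and dec_forward
.dec_atom_stage <- function(tp, P, batch, g, cfg, drop = NULL) {
  att_ids <- list()
  ge <- NULL
  if (batch$n_edges > 0) {
    ge <- ad_gather_rows(tp, g, batch$src)
    for (l in seq_len(cfg$n_layers)) {
      gi <- ad_gather_rows(tp, g, batch$dst)
      pair <- ad_cbind(tp, gi, ge)
      s <- ad_leaky_relu(tp, ad_add_bias(tp,
             ad_matmul(tp, .maybe_drop(tp, pair, drop), P("dec.att.W")),
             P("dec.att.b")))
      w <- ad_segment_softmax(tp, s, batch$dst)
      att_ids[[l]] <- w
      msg <- ad_matmul(tp, .maybe_drop(tp, ge, drop), P("dec.ctx.W"))
      C <- ad_elu(tp, ad_add_bias(tp,
             ad_segment_sum(tp, ad_colscale(tp, msg, w), batch$dst, batch$n_atoms),
             P("dec.ctx.b")))
      g_new <- ad_relu(tp, .ad_gru_step(tp, P, "dec.gru2", C, g))
      ge <- ad_leaky_relu(tp, ad_add_bias(tp,
              ad_matmul(tp, .maybe_drop(tp, pair, drop), P("dec.edge.W")),
              P("dec.edge.b")))
      g <- g_new
    }
  } else {
    for (l in seq_len(cfg$n_layers)) {
      C <- ad_const(tp, matrix(0, batch$n_atoms, cfg$hidden_dim))
      g <- ad_relu(tp, .ad_gru_step(tp, P, "dec.gru2", C, g))
    }
  }
  list(g = g, ge = ge, att_ids = att_ids)
}

#' Map final decoder states to chemical features
#'
#' The generation head: a 16-way softmax over element symbols per atom and,
#' when requested, per-directed-edge bond features (4-way softmax over bond
#' order plus sigmoids for the conjugated/in-ring flags).
#'
#' @param model A `cliffopt_model`.
#' @param g_atoms Final atom states.
#' @param g_edges Final directed-edge states (optional).
#' @param dst Receiver atom index per edge row (required with `g_edges`).
#' @return List with `atom_probs` (`N_a x 16` row-stochastic matrix) and
#'   `bond_feats` (or NULL).
#' @export
generate_features <- function(model, g_atoms, g_edges = NULL, dst = NULL) {
  tp <- ad_tape()
  P <- .param_binder(tp, model$params)
  g <- ad_const(tp, g_atoms)
  probs <- ad_softmax_rows(tp, ad_add_bias(tp,
             ad_matmul(tp, g, P("dec.atom.W")), P("dec.atom.b")))
  out <- list(atom_probs = ad_val(tp, probs), bond_feats = NULL)
  if (!is.null(g_edges)) {
    stopifnot(!is.null(dst))
    gi <- ad_gather_rows(tp, g, dst)
    z <- ad_leaky_relu(tp, ad_add_bias(tp,
           ad_matmul(tp, ad_cbind(tp, gi, ad_const(tp, g_edges)), P("dec.bond.W")),
           P("dec.bond.b")))
    op <- ad_softmax_rows(tp, ad_slice_cols(tp, z, 1:4))
    fp <- ad_sigmoid(tp, ad_slice_cols(tp, z, 5:6))
    out$bond_feats <- cbind(ad_val(tp, op), ad_val(tp, fp))
  }
  out
}

#' Decode a molecule from its (possibly perturbed) embedding
#'
#' The composite decoder: decompose, molecule-to-atom, atom-to-atom,
#' generate, with input embedding `f + direction * d`. `direction = 0`
#' yields the reconstruction branch; `+1` the optimization branch; `-1` the
#' reverse-optimization branch.
#'
#' @param model A `cliffopt_model`.
#' @param g A `mol_graph`.
#' @param d Perturbation vector (ignored when `direction = 0`; a zero
#'   vector is used when NULL).
#' @param direction One of `0`, `+1`, `-1`.
#' @param encoded Optional precomputed `list(f, H)` from [encode()].
#' @return List with `atom_probs`, `bond_feats` (NULL unless bond
#'   reconstruction is enabled), `gamma`, `f_in`.
#' @export
decode <- function(model, g, d = NULL, direction = 0, encoded = NULL) {
  stopifnot(direction %in% c(-1, 0, 1))
  cfg <- model$config
  if (is.null(encoded)) encoded <- encode(model, g)
  if (is.null(d)) d <- rep(0, length(encoded$f))
  f_in <- encoded$f + direction * d
  batch <- build_batch(list(g))
  tp <- ad_tape()
  P <- .param_binder(tp, model$params)
  dec <- dec_forward(tp, P, batch, ad_const(tp, encoded$H),
                     ad_const(tp, matrix(f_in, 1)), cfg, drop = NULL)
  list(
    atom_probs = ad_val(tp, dec$atom_probs),
    bond_feats = if (!is.null(dec$bond_feats)) ad_val(tp, dec$bond_feats) else NULL,
    gamma = as.vector(ad_val(tp, dec$gamma)),
    f_in = f_in
  )
}

# ---- reconstruction losses --------------------------------------------------

#' Weighted cross-entropy of atom-symbol reconstruction
#'
#' Each atom's negative log-likelihood is weighted by `1 - N_k/N_a`, the
#' complement of its element's share of the molecule, so abundant elements
#' (usually carbon) do not drown out the rare ones that carry most of the
#' chemistry. A molecule made of a single element therefore contributes
#' zero regardless of the prediction.
#'
#' @param atom_probs `N_a x 16` row-stochastic matrix.
#' @param atoms A `mol_graph`, or an integer vector of true symbol indices.
#' @return Nonnegative scalar.
#' @export
weighted_ce <- function(atom_probs, atoms) {
  k <- if (inherits(atoms, "mol_graph")) atoms$atoms$symbol_index else as.integer(atoms)
  n <- length(k)
  stopifnot(nrow(atom_probs) == n)
  counts <- table(k)
  w <- 1 - as.numeric(counts[as.character(k)]) / n
  p <- pmax(atom_probs[cbind(seq_len(n), k)], 1e-12)
  sum(w * (-log(p)))
}

#' Molecular reconstruction loss
#'
#' The per-molecule training loss of the decoder: the weighted atom-symbol
#' cross-entropy (and, when `include_bonds`, bond-feature cross-entropies
#' summed over adjacent pairs), normalized by the atom count.
#'
#' @param recon Output of [decode()] at `direction = 0`.
#' @param g The `mol_graph` being reconstructed.
#' @param include_bonds Include the bond-feature term (requires bond
#'   features in `recon`).
#' @return Nonnegative scalar.
#' @export
reconstruction_loss <- function(recon, g, include_bonds = FALSE) {
  loss <- weighted_ce(recon$atom_probs, g) / n_atoms(g)
  if (include_bonds) {
    if (is.null(recon$bond_feats)) stop("recon has no bond features")
    batch <- build_batch(list(g))
    bt <- batch$Bfeat
    pb <- pmin(pmax(recon$bond_feats, 1e-12), 1 - 1e-12)
    ce <- -rowSums(bt * log(pb)) - rowSums((1 - bt[, 5:6]) * log(1 - pb[, 5:6]))
    loss <- loss + sum(ce) / n_atoms(g)
  }
  loss
}

#' Fraction of molecules reconstructed exactly
#'
#' A molecule counts as reconstructed when the argmax of every atom's
#' symbol distribution (reconstruction branch, unperturbed embedding)
#' equals the true symbol.
#'
#' @param model A `cliffopt_model`.
#' @param data A data frame with a `smiles` column, or a list of
#'   `mol_graph` objects.
#' @return Fraction in `[0, 1]`.
#' @export
reconstruction_rate <- function(model, data) {
  graphs <- .as_graph_list(data)
  rate <- .recon_rate_graphs(model$params, model$config, graphs)
  rate
}

.as_graph_list <- function(data) {
  if (is.data.frame(data)) {
    g <- parse_smiles(data$smiles)
    if (inherits(g, "mol_graph")) list(g) else g
  } else if (inherits(data, "mol_graph")) list(data) else data
}

.recon_rate_graphs <- function(params, cfg, graphs, feats = NULL) {
  ok <- logical(length(graphs))
  for (chunk in split(seq_along(graphs), ceiling(seq_along(graphs) / 64))) {
    batch <- build_batch(graphs[chunk], feats[chunk])
    tp <- ad_tape()
    P <- .param_binder(tp, params)
    e <- enc_forward(tp, P, batch, cfg, drop = NULL)
    dec <- dec_forward(tp, P, batch, e$H, e$f, cfg, drop = NULL)
    probs <- ad_val(tp, dec$atom_probs)
    pred_sym <- max.col(probs, ties.method = "first")
    hit <- pred_sym == batch$sym
    ok[chunk] <- vapply(seq_along(chunk), function(m) all(hit[batch$mol == m]),
                        logical(1))
  }
  mean(ok)
}
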