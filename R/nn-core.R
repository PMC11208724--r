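# Parameter initialization and the batched forward passes of the three
# neural components: the attentive message-passing encoder, the two-slot
# bioactivity predictor, and the attentive graph reconstruction decoder.
# A "batch" is the disjoint union of several molecular graphs; per-molecule
# quantities are handled with segment (grouped) operations, so molecules of
# different sizes share one tape.

.ATOM_FDIM <- 29L
.BOND_FDIM <- 6L
.N_SYMBOLS <- 16L

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

.zeros_row <- function(d) matrix(0, 1, d)

.gru_init <- function(din, dh) {
  out <- list()
  for (gate in c("z", "r", "h")) {
    out[[paste0("Wx", gate)]] <- .glorot(din, dh)
    out[[paste0("Wh", gate)]] <- .glorot(dh, dh)
    out[[paste0("b", gate)]] <- .zeros_row(dh)
  }
  out
}

.flatten_params <- function(lst, prefix = "") {
  out <- list()
  for (nm in names(lst)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(lst[[nm]])) out <- c(out, .flatten_params(lst[[nm]], full))
    else out[[full]] <- lst[[nm]]
  }
  out
}

# All learned parameters as a flat named list of matrices. Uses the current
# RNG state; callers seed beforehand.
init_params <- function(cfg) {
  d <- cfg$hidden_dim
  p <- list()
  p$enc.in <- list(W = .glorot(.ATOM_FDIM, d), b = .zeros_row(d))
  for (l in seq_len(cfg$n_layers)) {
    p[[sprintf("enc.l%d", l)]] <- list(
      att = list(W = .glorot(2 * d + .BOND_FDIM, 1), b = .zeros_row(1)),
      msg = list(W = .glorot(d + .BOND_FDIM, d), b = .zeros_row(d)),
      gru = .gru_init(d, d)
    )
  }
  p$pred.h <- list(W = .glorot(2 * d, d), b = .zeros_row(d))
  p$pred.out <- list(W = .glorot(d, 1), b = .zeros_row(1))
  p$dec.rel <- list(W = .glorot(2 * d, d), b = .zeros_row(d))
  p$dec.gru1 <- .gru_init(d, d)
  p$dec.att <- list(W = .glorot(2 * d, 1), b = .zeros_row(1))
  p$dec.ctx <- list(W = .glorot(d, d), b = .zeros_row(d))
  p$dec.gru2 <- .gru_init(d, d)
  p$dec.edge <- list(W = .glorot(2 * d, d), b = .zeros_row(d))
  p$dec.atom <- list(W = .glorot(d, .N_SYMBOLS), b = .zeros_row(.N_SYMBOLS))
  p$dec.bond <- list(W = .glorot(2 * d, .BOND_FDIM), b = .zeros_row(.BOND_FDIM))
  .flatten_params(p)
}

# caches leaf ids so each parameter appears once per tape
.param_binder <- function(tp, params) {
  cache <- new.env(parent = emptyenv())
  function(name) {
    if (!is.null(cache[[name]])) return(cache[[name]])
    v <- params[[name]]
    if (is.null(v)) stop(sprintf("unknown parameter '%s'", name))
    id <- ad_leaf(tp, v, name)
    cache[[name]] <- id
    id
  }
}

# dropout mask factory: NULL in eval mode
.dropper <- function(rate, training) {
  if (!training || rate <= 0) return(NULL)
  function(nr, nc) {
    matrix(stats::rbinom(nr * nc, 1, 1 - rate), nr, nc) / (1 - rate)
  }
}

.maybe_drop <- function(tp, id, drop) {
  force(id)
  if (is.null(drop)) return(id)
  v <- ad_val(tp, id)
  ad_mask(tp, id, drop(nrow(v), ncol(v)))
}

# ---- batch assembly ---------------------------------------------------------

# Disjoint union of graphs: stacked atom features, directed edge list with
# bond features, molecule membership.
build_batch <- function(graphs, feats = NULL) {
  if (is.null(feats)) feats <- lapply(graphs, featurize)
  n_per <- vapply(graphs, n_atoms, integer(1))
  offset <- cumsum(c(0L, utils::head(n_per, -1)))
  X <- do.call(rbind, lapply(feats, `[[`, "atoms"))
  mol <- rep(seq_along(graphs), n_per)
  src <- integer(0); dst <- integer(0); bf <- NULL
  bond_of_edge <- integer(0); mol_of_edge <- integer(0)
  for (m in seq_along(graphs)) {
    g <- graphs[[m]]
    nb <- nrow(g$bonds)
    if (nb == 0) next
    i <- g$bonds$i + offset[m]; j <- g$bonds$j + offset[m]
    src <- c(src, j, i)          # message j -> i and i -> j
    dst <- c(dst, i, j)
    bf <- rbind(bf, feats[[m]]$bonds, feats[[m]]$bonds)
    bond_of_edge <- c(bond_of_edge, seq_len(nb), seq_len(nb))
    mol_of_edge <- c(mol_of_edge, rep(m, 2 * nb))
  }
  list(
    graphs = graphs, X = X, mol = mol, n_mol = length(graphs),
    n_atoms = nrow(X), n_per = n_per, offset = offset,
    src = src, dst = dst, Bfeat = bf, n_edges = length(src),
    bond_of_edge = bond_of_edge, mol_of_edge = mol_of_edge,
    sym = unlist(lapply(graphs, function(g) g$atoms$symbol_index), use.names = FALSE)
  )
}

.ad_gru_step <- function(tp, P, prefix, x, h) {
  g <- function(nm) P(paste0(prefix, ".", nm))
  z <- ad_sigmoid(tp, ad_add(tp,
        ad_add_bias(tp, ad_matmul(tp, x, g("Wxz")), g("bz")),
        ad_matmul(tp, h, g("Whz"))))
  r <- ad_sigmoid(tp, ad_add(tp,
        ad_add_bias(tp, ad_matmul(tp, x, g("Wxr")), g("br")),
        ad_matmul(tp, h, g("Whr"))))
  htil <- ad_tanh(tp, ad_add(tp,
        ad_add_bias(tp, ad_matmul(tp, x, g("Wxh")), g("bh")),
        ad_matmul(tp, ad_mul(tp, r, h), g("Whh"))))
  # h' = (1 - z) * h + z * htil
  ad_add(tp,
         ad_mul(tp, ad_affine(tp, z, -1, 1), h),
         ad_mul(tp, z, htil))
}

# ---- encoder ----------------------------------------------------------------

# returns node ids: H (atoms x d), f (molecules x d)
enc_forward <- function(tp, P, batch, cfg, drop = NULL) {
  X <- ad_const(tp, batch$X)
  H <- ad_relu(tp, ad_add_bias(tp, ad_matmul(tp, X, P("enc.in.W")),
                               P("enc.in.b")))
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc.l%d", l)
    if (batch$n_edges > 0) {
      B <- ad_const(tp, batch$Bfeat)
      hs <- ad_gather_rows(tp, H, batch$src)
      hd <- ad_gather_rows(tp, H, batch$dst)
      sc_in <- ad_cbind(tp, ad_cbind(tp, hd, hs), B)
      s <- ad_leaky_relu(tp, ad_add_bias(tp,
             ad_matmul(tp, .maybe_drop(tp, sc_in, drop), P(paste0(pre, ".att.W"))),
             P(paste0(pre, ".att.b"))))
      w <- ad_segment_softmax(tp, s, batch$dst)
      msg <- ad_add_bias(tp,
               ad_matmul(tp, .maybe_drop(tp, ad_cbind(tp, hs, B), drop),
                         P(paste0(pre, ".msg.W"))),
               P(paste0(pre, ".msg.b")))
      C <- ad_elu(tp, ad_segment_sum(tp, ad_colscale(tp, msg, w),
                                     batch$dst, batch$n_atoms))
    } else {
      C <- ad_const(tp, matrix(0, batch$n_atoms, cfg$hidden_dim))
    }
    H <- ad_relu(tp, .ad_gru_step(tp, P, paste0(pre, ".gru"), C, H))
  }
  f <- ad_segment_sum(tp, H, batch$mol, batch$n_mol)  # sum readout
  list(H = H, f = f)
}

# ---- predictor --------------------------------------------------------------

# f1, f2: (n x d) node ids; returns (n x 1) raw prediction / logit
pred_forward <- function(tp, P, f1, f2) {
  h <- ad_relu(tp, ad_add_bias(tp,
         ad_matmul(tp, ad_cbind(tp, f1, f2), P("pred.h.W")), P("pred.h.b")))
  ad_add_bias(tp, ad_matmul(tp, h, P("pred.out.W")), P("pred.out.b"))
}

# ---- decoder ----------------------------------------------------------------

# fin: (n_mol x d) node id of the (possibly perturbed) molecular embeddings.
# Returns node ids: gamma (atoms x 1), atom_probs (atoms x 16), and, when
# cfg$include_bonds, bond_feats (directed edges x 6).
dec_forward <- function(tp, P, batch, H, fin, cfg, drop = NULL) {
  d <- cfg$hidden_dim
  fin_atoms <- ad_gather_rows(tp, fin, batch$mol)
  # embedding decomposition: softmax over atoms of <f_in, h_i>
  scores <- ad_rowsums(tp, ad_mul(tp, fin_atoms, H))
  gamma <- ad_segment_softmax(tp, scores, batch$mol)
  # molecule-to-atom: g^T = gamma_i f_in + h_i, then T GRU refinements
  g <- ad_add(tp, ad_colscale(tp, fin_atoms, gamma), H)
  gT <- g
  for (t in seq_len(cfg$t_steps)) {
    rel_in <- .maybe_drop(tp, ad_cbind(tp, fin_atoms, g), drop)
    r <- ad_elu(tp, ad_add_bias(tp, ad_matmul(tp, rel_in, P("dec.rel.W")),
                                P("dec.rel.b")))
    g <- ad_relu(tp, .ad_gru_step(tp, P, "dec.gru1", r, g))
  }
  g0_atoms <- g
  # atom-to-atom refinement over L layers with edge states (shared stage)
  st <- .dec_atom_stage(tp, P, batch, g, cfg, drop)
  g <- st$g
  atom_logits <- ad_add_bias(tp, ad_matmul(tp, g, P("dec.atom.W")),
                             P("dec.atom.b"))
  atom_probs <- ad_softmax_rows(tp, atom_logits)
  out <- list(gamma = gamma, atom_probs = atom_probs, gT = gT,
              g0_atoms = g0_atoms, g_final = g, att_ids = st$att_ids)
  if (cfg$include_bonds && batch$n_edges > 0) {
    gi <- ad_gather_rows(tp, g, batch$dst)
    z <- ad_leaky_relu(tp, ad_add_bias(tp,
           ad_matmul(tp, .maybe_drop(tp, ad_cbind(tp, gi, st$ge), drop),
                     P("dec.bond.W")),
           P("dec.bond.b")))
    order_p <- ad_softmax_rows(tp, ad_slice_cols(tp, z, 1:4))
    flag_p <- ad_sigmoid(tp, ad_slice_cols(tp, z, 5:6))
    out$bond_feats <- ad_cbind(tp, order_p, flag_p)
  }
  out
}

# ---- losses (tape nodes) ----------------------------------------------------

# weighted cross-entropy coefficients (1 - N_{K_i}/N_a) for every atom of
# the batch, plus the per-molecule 1/N_a normalization
.wce_coefs <- function(batch) {
  w <- numeric(batch$n_atoms)
  for (m in seq_len(batch$n_mol)) {
    idx <- which(batch$mol == m)
    sym <- batch$sym[idx]
    counts <- table(sym)
    w[idx] <- 1 - as.numeric(counts[as.character(sym)]) / length(idx)
  }
  w
}

# mean over molecules of the per-molecule reconstruction loss
recon_loss_node <- function(tp, batch, atom_probs, bond_feats = NULL) {
  w <- .wce_coefs(batch)
  coef <- w / batch$n_per[batch$mol] / batch$n_mol
  p <- ad_gather_entries(tp, atom_probs, seq_len(batch$n_atoms), batch$sym)
  nll <- ad_affine(tp, ad_log(tp, p), -1)
  loss <- ad_sum(tp, ad_mul(tp, nll, ad_const(tp, matrix(coef, ncol = 1))))
  if (!is.null(bond_feats)) {
    bt <- batch$Bfeat
    pb <- ad_val(tp, bond_feats)
    ecoef <- 1 / batch$n_per[batch$mol_of_edge] / batch$n_mol
    # categorical CE on the order block + BCE on the flags
    lp <- ad_log(tp, bond_feats)
    lq <- ad_log(tp, ad_affine(tp, bond_feats, -1, 1))
    ce_pos <- ad_mul(tp, lp, ad_const(tp, bt))
    flag_mask <- matrix(0, nrow(bt), 6); flag_mask[, 5:6] <- 1
    ce_neg <- ad_mul(tp, lq, ad_const(tp, (1 - bt) * flag_mask))
    per_edge <- ad_affine(tp, ad_rowsums(tp, ad_add(tp, ce_pos, ce_neg)), -1)
    bond_term <- ad_sum(tp, ad_mul(tp, per_edge,
                                   ad_const(tp, matrix(ecoef, ncol = 1))))
    loss <- ad_add(tp, loss, bond_term)
  }
  loss
}

# task loss on predictions (n x 1 node) against numeric labels
bio_loss_node <- function(tp, preds, y, task) {
  n <- length(y)
  if (task == "regression") {
    e <- ad_sub(tp, preds, ad_const(tp, matrix(y, ncol = 1)))
    ad_affine(tp, ad_sum(tp, ad_mul(tp, e, e)), 1 / n)
  } else {
    p <- ad_sigmoid(tp, preds)
    pos <- ad_mul(tp, ad_log(tp, p), ad_const(tp, matrix(y, ncol = 1)))
    neg <- ad_mul(tp, ad_log(tp, ad_affine(tp, p, -1, 1)),
                  ad_const(tp, matrix(1 - y, ncol = 1)))
    ad_affine(tp, ad_sum(tp, ad_add(tp, pos, neg)), -1 / n)
  }
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
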