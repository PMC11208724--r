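# Joint training of encoder, predictor and decoder under the min-max
# objective: task loss + lambda1 * adversarial stabilization + lambda2 *
# (reconstruction + validity). The max over the perturbation is realized by
# the one-step adversarial construction; the min is plain first-order
# descent (Adam) under a warm-up/cool-down schedule.

#' Learning-rate schedule with warm-up and cool-down
#'
#' Linear ramp from zero to `base_rate` over the first
#' `warmup_fraction` of steps, then linear decay back to zero.
#'
#' @param step Current step (0-based, up to `total_steps`).
#' @param total_steps Total number of optimization steps.
#' @param base_rate Peak learning rate.
#' @param warmup_fraction Fraction of steps spent ramping up.
#' @return The learning rate at `step`.
#' @export
lr_schedule <- function(step, total_steps, base_rate, warmup_fraction = 0.1) {
  stopifnot(step >= 0, step <= total_steps)
  w <- max(round(total_steps * warmup_fraction), 1)
  if (step <= w) return(base_rate * step / w)
  base_rate * (total_steps - step) / (total_steps - w)
}

# one gradient step on a batch; returns updated params/opt state + components
.train_step <- function(params, opt, cfg, batch, y, lr, check_invariants = FALSE) {
  drop <- .dropper(cfg$dropout, training = TRUE)
  tp <- ad_tape()
  P <- .param_binder(tp, params)
  e <- enc_forward(tp, P, batch, cfg, drop)
  f_val <- ad_val(tp, e$f)
  # one-step adversarial direction (separate tape; value only, no gradient)
  afse <- .afse_batch(params, cfg, f_val)
  sgn <- .orient_signs(params, f_val, afse$d)
  d_orient <- afse$d * sgn
  pred0 <- pred_forward(tp, P, e$f, e$f)
  l_bio <- bio_loss_node(tp, pred0, y, cfg$task)
  predd <- pred_forward(tp, P, e$f, ad_add(tp, e$f, ad_const(tp, afse$d)))
  err <- ad_sub(tp, pred0, predd)
  l_afse <- ad_affine(tp, ad_sum(tp, ad_mul(tp, err, err)), 1 / batch$n_mol)
  # reconstruction branch (clean embedding)
  rec <- dec_forward(tp, P, batch, e$H, e$f, cfg, drop)
  l_recon <- recon_loss_node(tp, batch, rec$atom_probs,
                             if (cfg$include_bonds) rec$bond_feats else NULL)
  # optimization branch (oriented perturbed embedding) and validity penalty
  f_opt <- ad_add(tp, e$f, ad_const(tp, d_orient))
  opt_dec <- dec_forward(tp, P, batch, e$H, f_opt, cfg, drop)
  sel <- .select_batch(batch, ad_val(tp, rec$atom_probs),
                       ad_val(tp, opt_dec$atom_probs), cfg$p0)
  bad <- which(sel$selected & !sel$valid)
  if (length(bad)) {
    rows <- batch$offset[bad] + sel$i_star[bad]
    p_bad <- ad_gather_entries(tp, opt_dec$atom_probs, rows, sel$k_star[bad])
    one_minus <- ad_affine(tp, p_bad, -1, 1)
    l_val <- ad_affine(tp, ad_sum(tp, ad_log(tp, one_minus)), -1 / batch$n_mol)
  } else {
    l_val <- ad_const(tp, matrix(0))
  }
  total <- ad_add(tp, l_bio,
            ad_add(tp, ad_affine(tp, l_afse, cfg$lambda1),
              ad_affine(tp, ad_add(tp, l_recon, l_val), cfg$lambda2)))
  tv <- as.numeric(ad_val(tp, total))
  if (!is.finite(tv)) {
    stop("diverged: non-finite training loss; consider a lower base_lr")
  }
  if (check_invariants) {
    .assert_simplex_invariants(tp, rec, opt_dec, batch)
  }
  grads <- ad_backward(tp, total)
  grads$`__r__` <- NULL
  stepres <- adam_step(params, grads, opt, lr)
  list(params = stepres$params, opt = stepres$state,
       components = c(bio = as.numeric(ad_val(tp, l_bio)),
                      afse = as.numeric(ad_val(tp, l_afse)),
                      recon = as.numeric(ad_val(tp, l_recon)),
                      val = as.numeric(ad_val(tp, l_val)),
                      total = tv))
}

.orient_signs <- function(params, f_val, d_mat) {
  base <- .predict_mat(params, f_val)
  pert <- .predict_mat(params, f_val, d_mat)
  ifelse(pert - base >= 0, 1, -1)
}

# per-molecule (i*, k*) selection + valence check on a batch; vectorized
# across atoms (equivalent to select_key_atom/select_replacement per
# molecule, which the property tests assert)
.select_batch <- function(batch, p_recon, p_opt, p0) {
  n_mol <- batch$n_mol
  i_star <- rep(NA_integer_, n_mol)
  k_star <- rep(NA_integer_, n_mol)
  conf <- rep(NA_real_, n_mol)
  valid <- rep(NA, n_mol)
  masked <- p_opt
  masked[p_recon >= p0] <- -Inf  # only elements outside the confusable set
  atom_best <- masked[, 1]
  for (k in 2:ncol(masked)) atom_best <- pmax(atom_best, masked[, k])
  rows_by_mol <- split(seq_len(batch$n_atoms), batch$mol)
  for (m in seq_len(n_mol)) {
    rows <- rows_by_mol[[m]]
    best <- atom_best[rows]
    if (!any(is.finite(best))) next
    gi <- rows[which.max(best)]
    i_star[m] <- match(gi, rows)
    row <- p_opt[gi, ]
    cand <- which(row >= p0)
    cand <- cand[cand != batch$sym[gi]]
    if (!length(cand)) next
    k <- cand[which.max(row[cand])]
    k_star[m] <- k
    conf[m] <- row[k]
    valid[m] <- check_assignment_valid(batch$graphs[[m]], i_star[m], k) == 0
  }
  list(i_star = i_star, k_star = k_star, confidence = conf,
       selected = !is.na(k_star), valid = valid)
}

.assert_simplex_invariants <- function(tp, rec, opt_dec, batch, tol = 1e-6) {
  for (dec in list(rec, opt_dec)) {
    gam <- as.vector(ad_val(tp, dec$gamma))
    gs <- rowsum(gam, batch$mol)
    if (any(abs(gs - 1) > tol) || any(gam <= 0)) {
      stop("invariant violation: decomposition weights are not a simplex")
    }
    for (wid in dec$att_ids) {
      w <- as.vector(ad_val(tp, wid))
      ws <- rowsum(w, batch$dst)
      if (any(abs(ws - 1) > tol)) {
        stop("invariant violation: attention weights do not sum to 1")
      }
    }
    ap <- ad_val(tp, dec$atom_probs)
    if (any(abs(rowSums(ap) - 1) > tol) || any(ap <= 0)) {
      stop("invariant violation: atom probability rows are not a simplex")
    }
  }
  invisible(TRUE)
}

# evaluation-mode rates over a set of graphs
.eval_rates <- function(params, cfg, graphs, feats = NULL, chunk_size = 64) {
  n <- length(graphs)
  recon_ok <- logical(n)
  selected <- logical(n)
  valid <- logical(n)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / chunk_size))) {
    batch <- build_batch(graphs[chunk], feats[chunk])
    tp <- ad_tape()
    P <- .param_binder(tp, params)
    e <- enc_forward(tp, P, batch, cfg, drop = NULL)
    f_val <- ad_val(tp, e$f)
    afse <- .afse_batch(params, cfg, f_val)
    d_orient <- afse$d * .orient_signs(params, f_val, afse$d)
    rec <- dec_forward(tp, P, batch, e$H, e$f, cfg, drop = NULL)
    f_opt <- ad_add(tp, e$f, ad_const(tp, d_orient))
    opt_dec <- dec_forward(tp, P, batch, e$H, f_opt, cfg, drop = NULL)
    p_rec <- ad_val(tp, rec$atom_probs)
    pred_sym <- max.col(p_rec, ties.method = "first")
    hit <- pred_sym == batch$sym
    recon_ok[chunk] <- vapply(seq_along(chunk),
                              function(m) all(hit[batch$mol == m]), logical(1))
    sel <- .select_batch(batch, p_rec, ad_val(tp, opt_dec$atom_probs), cfg$p0)
    selected[chunk] <- sel$selected
    valid[chunk] <- ifelse(is.na(sel$valid), FALSE, sel$valid)
  }
  list(recon_rate = mean(recon_ok),
       validity_rate = if (any(selected)) mean(valid[selected]) else NA_real_,
       n_selected = sum(selected))
}

#' Fit the joint prediction + optimization model
#'
#' Trains the encoder, the two-slot bioactivity predictor and the graph
#' reconstruction decoder jointly. Per batch: encode, draw the one-step
#' adversarial perturbation, then descend on
#' `L_bio + lambda1 * L_afse + lambda2 * (L_recon + L_val)`.
#' Per epoch the training-set reconstruction and validity rates and a
#' validation metric are recorded; the returned model carries the
#' parameters of the epoch with the highest `reconstruction rate +
#' validity rate` (the best-model rule) unless `select_best = FALSE`.
#'
#' @param data Data frame with columns `smiles` and `activity` (pActivity
#'   for regression, 0/1 for classification).
#' @param config A [cliffopt_config()].
#' @param select_best Keep the best epoch's parameters (default) rather
#'   than the last.
#' @param early_stop_recon Optional reconstruction-rate level at which
#'   training stops early (e.g. 0.95); the learning-rate schedule is still
#'   laid out over `config$epochs`.
#' @param check_invariants Assert the simplex/normalization invariants of
#'   the decoder after every training step (slower; used by the test
#'   suite).
#' @param verbose Print one line per epoch.
#' @return A `cliffopt_model`: list with `params`, `final_params`,
#'   `best_epoch`, `config`, `history` (tibble, one row per epoch),
#'   `vocab_hash`.
#' @export
cliffopt_fit <- function(data, config = cliffopt_config(),
                         select_best = TRUE, check_invariants = FALSE,
                         early_stop_recon = NULL, verbose = FALSE) {
  stopifnot(is.data.frame(data), "smiles" %in% names(data),
            "activity" %in% names(data))
  cfg <- config
  set.seed(cfg$seed)
  graphs <- parse_smiles(data$smiles)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  feats <- lapply(graphs, featurize)
  y <- as.numeric(data$activity)
  if (cfg$task == "regression" && any(abs(y) > 15, na.rm = TRUE)) {
    warning("activities look larger than a pActivity scale; expected -log10 molar units")
  }
  n <- length(graphs)
  n_val <- max(if (cfg$val_frac > 0 && n >= 10) round(cfg$val_frac * n) else 0, 0)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- init_params(cfg)
  opt <- adam_state(params)
  steps_per_epoch <- ceiling(length(tr_idx) / cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$epochs
  step <- 0L
  history <- vector("list", cfg$epochs)
  best_score <- -Inf
  best_epoch <- NA_integer_
  best_params <- params
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    comps <- c(bio = 0, afse = 0, recon = 0, val = 0, total = 0)
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      step <- step + 1L
      lr <- lr_schedule(step, total_steps, cfg$base_lr, cfg$warmup_frac)
      batch <- build_batch(graphs[b], feats[b])
      res <- .train_step(params, opt, cfg, batch, y[b], lr, check_invariants)
      params <- res$params
      opt <- res$opt
      comps <- comps + res$components
    }
    comps <- comps / steps_per_epoch
    rates <- .eval_rates(params, cfg, graphs[tr_idx], feats[tr_idx])
    vm <- .val_metric(params, cfg, graphs[val_idx], feats[val_idx], y[val_idx])
    history[[ep]] <- tibble::tibble(
      epoch = ep, l_bio = comps[["bio"]], l_afse = comps[["afse"]],
      l_recon = comps[["recon"]], l_val = comps[["val"]],
      total = comps[["total"]], reconstruction_rate = rates$recon_rate,
      validity_rate = rates$validity_rate, val_metric = vm, lr = lr
    )
    score <- rates$recon_rate +
      (if (is.na(rates$validity_rate)) 0 else rates$validity_rate)
    if (score > best_score) {
      best_score <- score
      best_epoch <- ep
      best_params <- params
    }
    if (verbose) {
      message(sprintf(
        "epoch %3d  total %.4f  bio %.4f  recon_rate %.3f  validity %.3f",
        ep, comps[["total"]], comps[["bio"]], rates$recon_rate,
        ifelse(is.na(rates$validity_rate), -1, rates$validity_rate)))
    }
    if (!is.null(early_stop_recon) && rates$recon_rate >= early_stop_recon) break
  }
  history <- dplyr::bind_rows(history)
  model <- structure(
    list(params = if (select_best) best_params else params,
         final_params = params, best_params = best_params,
         best_epoch = best_epoch,
         config = cfg, history = history, vocab_hash = vocabulary_hash(),
         n_train = length(tr_idx), n_val = length(val_idx)),
    class = "cliffopt_model"
  )
  model
}

.val_metric <- function(params, cfg, graphs, feats, y) {
  if (length(graphs) < 2) return(NA_real_)
  preds <- numeric(length(graphs))
  for (chunk in split(seq_along(graphs), ceiling(seq_along(graphs) / 64))) {
    e_f <- ad_val_of_f(params, cfg, graphs[chunk], feats[chunk])
    preds[chunk] <- .predict_mat(params, e_f)
  }
  if (cfg$task == "regression") {
    if (stats::sd(y) == 0 || stats::sd(preds) == 0) return(NA_real_)
    stats::cor(y, preds)^2
  } else {
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(y, preds, quiet = TRUE, direction = "<")))
  }
}

ad_val_of_f <- function(params, cfg, graphs, feats = NULL) {
  batch <- build_batch(graphs, feats)
  tp <- ad_tape()
  P <- .param_binder(tp, params)
  e <- enc_forward(tp, P, batch, cfg, drop = NULL)
  ad_val(tp, e$f)
}

#' @export
print.cliffopt_model <- function(x, ...) {
  cat(sprintf(
    "<cliffopt_model: %s, hidden_dim %d, %d epochs, best epoch %s>\n",
    x$config$task, x$config$hidden_dim, nrow(x$history),
    format(x$best_epoch)))
  invisible(x)
}

#' Total training objective on a dataset (evaluation mode)
#'
#' Recomputes the four loss components and their weighted total on a
#' molecule table with the current parameters, dropout off.
#'
#' @param model A `cliffopt_model`.
#' @param data Data frame with `smiles` and `activity`.
#' @return A named list: `total`, `bio`, `afse`, `recon`, `val`.
#' @export
total_objective <- function(model, data) {
  cfg <- model$config
  graphs <- .as_graph_list(data)
  y <- as.numeric(data$activity)
  comps <- c(bio = 0, afse = 0, recon = 0, val = 0, total = 0)
  nb <- 0L
  for (chunk in split(seq_along(graphs), ceiling(seq_along(graphs) / 64))) {
    batch <- build_batch(graphs[chunk])
    tp <- ad_tape()
    P <- .param_binder(tp, model$params)
    e <- enc_forward(tp, P, batch, cfg, drop = NULL)
    f_val <- ad_val(tp, e$f)
    afse <- .afse_batch(model$params, cfg, f_val)
    d_orient <- afse$d * .orient_signs(model$params, f_val, afse$d)
    pred0 <- pred_forward(tp, P, e$f, e$f)
    l_bio <- bio_loss_node(tp, pred0, y[chunk], cfg$task)
    predd <- pred_forward(tp, P, e$f, ad_add(tp, e$f, ad_const(tp, afse$d)))
    err <- ad_sub(tp, pred0, predd)
    l_afse <- ad_affine(tp, ad_sum(tp, ad_mul(tp, err, err)), 1 / batch$n_mol)
    rec <- dec_forward(tp, P, batch, e$H, e$f, cfg, drop = NULL)
    l_recon <- recon_loss_node(tp, batch, rec$atom_probs,
                               if (cfg$include_bonds) rec$bond_feats else NULL)
    f_opt <- ad_add(tp, e$f, ad_const(tp, d_orient))
    opt_dec <- dec_forward(tp, P, batch, e$H, f_opt, cfg, drop = NULL)
    p_opt <- ad_val(tp, opt_dec$atom_probs)
    sel <- .select_batch(batch, ad_val(tp, rec$atom_probs), p_opt, cfg$p0)
    lv <- 0
    bad <- which(sel$selected & !sel$valid)
    for (m in bad) {
      lv <- lv + validity_loss(
        p_opt[batch$mol == m, , drop = FALSE], sel$i_star[m], sel$k_star[m], 1)
    }
    comps <- comps + c(bio = as.numeric(ad_val(tp, l_bio)),
                       afse = as.numeric(ad_val(tp, l_afse)),
                       recon = as.numeric(ad_val(tp, l_recon)),
                       val = lv / batch$n_mol, total = 0)
    nb <- nb + 1L
  }
  comps <- comps / nb
  comps[["total"]] <- comps[["bio"]] + cfg$lambda1 * comps[["afse"]] +
    cfg$lambda2 * (comps[["recon"]] + comps[["val"]])
  as.list(comps)
}

#' Validity rate of the selection pipeline
#'
#' Among molecules for which a substitution (i*, k*) is actually selected,
#' the fraction whose selected assignment passes the valence check.
#' Molecules with no selected candidate are excluded from the denominator;
#' with no selections at all the rate is `NA` (not applicable).
#'
#' @param model A `cliffopt_model`.
#' @param data Data frame with `smiles`, or list of graphs.
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
validity_rate <- function(model, data) {
  graphs <- .as_graph_list(data)
  .eval_rates(model$params, model$config, graphs)$validity_rate
}

#' Pick the best epoch by reconstruction + validity rate
#'
#' The best-model rule: the checkpoint maximizing the sum of the training
#' reconstruction rate and validity rate (a missing validity rate counts as
#' zero), earliest epoch on ties.
#'
#' @param x A `cliffopt_model`, or a data frame with columns
#'   `reconstruction_rate` and `validity_rate`.
#' @param checkpoints Optional list of parameter sets aligned with the
#'   history rows; returned instead of the index when supplied.
#' @return For a model: the model with the best parameters active. For a
#'   history: the best epoch index, or `checkpoints[[best]]`.
#' @export
select_best_model <- function(x, checkpoints = NULL) {
  if (inherits(x, "cliffopt_model")) {
    # refit models always carry the best checkpoint
    x$params <- if (!is.null(x$best_params)) x$best_params else x$params
    return(x)
  }
  score <- x$reconstruction_rate +
    ifelse(is.na(x$validity_rate), 0, x$validity_rate)
  best <- which.max(score)  # which.max takes the earliest maximum
  if (!is.null(checkpoints)) checkpoints[[best]] else best
}
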