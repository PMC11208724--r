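# Maximum-posterior selection of the key atom and replacement element, the
# validity loss, and the end-to-end single-molecule optimization (forward
# toward higher predicted activity, reverse toward lower).

#' Posterior element tables for a molecule
#'
#' Runs the decoder twice: once on the clean embedding (reconstruction
#' posterior `P_f(k|i)`) and once on the perturbed embedding
#' (optimization posterior). A fresh adversarial perturbation is drawn with
#' the current RNG state and oriented so that `forward` moves predicted
#' activity up and `reverse` down.
#'
#' @param model A `cliffopt_model`.
#' @param g A `mol_graph`.
#' @param direction `"forward"` or `"reverse"`.
#' @param eta,epsilon Perturbation controls; default to the model
#'   configuration.
#' @return A list of class `posterior_table`: `P_recon`, `P_opt`
#'   (`N_a x 16` row-stochastic matrices), `sym` (original symbol indices),
#'   `d` (the oriented perturbation actually applied), `flat`.
#' @export
posterior_tables <- function(model, g, direction = c("forward", "reverse"),
                             eta = model$config$eta,
                             epsilon = model$config$epsilon) {
  direction <- match.arg(direction)
  enc <- encode(model, g)
  pert <- adversarial_perturbation(model, enc$f, eta = eta, epsilon = epsilon)
  d <- pert$d
  if (!pert$flat) d <- orient_perturbation(model, enc$f, d) * d
  s <- if (direction == "forward") 1 else -1
  rec <- decode(model, g, d = NULL, direction = 0, encoded = enc)
  opt <- decode(model, g, d = d, direction = s, encoded = enc)
  structure(
    list(P_recon = rec$atom_probs, P_opt = opt$atom_probs,
         sym = g$atoms$symbol_index, d = s * d, flat = pert$flat,
         direction = direction),
    class = "posterior_table"
  )
}

#' Confusable element set of one atom
#'
#' Elements whose reconstruction confidence reaches the threshold: either
#' the atom's true element or elements the decoder systematically confuses
#' with it. Substitution candidates must lie outside this set.
#'
#' @param P_recon `N_a x 16` reconstruction posterior.
#' @param i Atom index.
#' @param p0 Confidence threshold in (0, 1).
#' @return Integer vector of symbol indices (possibly empty).
#' @export
confusable_set <- function(P_recon, i, p0) {
  which(P_recon[i, ] >= p0)
}

#' Select the key atom for substitution
#'
#' For each atom, consider only elements outside its confusable set and
#' take the best optimization confidence among them; the key atom is the
#' atom maximizing this quantity (ties broken toward the lowest atom
#' index). Returns `NA` when every atom's admissible element set is empty.
#'
#' @param table A `posterior_table` (or any list with `P_recon`, `P_opt`).
#' @param p0 Confidence threshold.
#' @return Atom index or `NA_integer_`.
#' @export
select_key_atom <- function(table, p0) {
  n <- nrow(table$P_opt)
  best <- rep(-Inf, n)
  for (i in seq_len(n)) {
    adm <- setdiff(seq_len(16L), confusable_set(table$P_recon, i, p0))
    if (length(adm)) best[i] <- max(table$P_opt[i, adm])
  }
  if (all(!is.finite(best))) return(NA_integer_)
  which.max(best)  # ties -> lowest index
}

#' Select the replacement element at the key atom
#'
#' Among elements whose optimization confidence at the key atom reaches the
#' threshold and that differ from the atom's original element, pick the
#' most confident (ties broken toward the lowest symbol index). `NA` when
#' no candidate clears the threshold — low-confidence optimizations are
#' dropped rather than emitted.
#'
#' @param table A `posterior_table` with `sym` (original symbol indices),
#'   or pass `original` explicitly.
#' @param i_star Key atom index.
#' @param p0 Confidence threshold.
#' @param original Original symbol index of the key atom (defaults to
#'   `table$sym[i_star]`).
#' @return Symbol index or `NA_integer_`.
#' @export
select_replacement <- function(table, i_star, p0, original = NULL) {
  if (is.null(original)) original <- table$sym[i_star]
  row <- table$P_opt[i_star, ]
  cand <- setdiff(which(row >= p0), original)
  if (!length(cand)) return(NA_integer_)
  cand[which.max(row[cand])]
}

#' Validity loss for a selected substitution
#'
#' Valid selections cost nothing; an invalid selection is penalized by
#' `-log(1 - p)` where `p` is the optimization confidence of the invalid
#' assignment, so the more confidently the decoder proposes an impossible
#' element the larger the penalty.
#'
#' @param P_opt Optimization posterior matrix.
#' @param i_star,k_star Selected atom and element indices.
#' @param val_flag `0` (valid) or `1` (invalid), as returned by
#'   [check_assignment_valid()].
#' @return Nonnegative scalar.
#' @export
validity_loss <- function(P_opt, i_star, k_star, val_flag) {
  if (val_flag == 0) return(0)
  -log(pmax(1 - P_opt[i_star, k_star], 1e-12))
}

#' Optimize one ligand by a single-atom substitution
#'
#' The full selection pipeline: posterior tables, key-atom selection,
#' replacement selection, valence check; the substituted molecule is
#' emitted only when a candidate exists and is chemically valid, so fewer
#' molecules may be generated than anchors supplied.
#'
#' @param model A trained `cliffopt_model`.
#' @param g A `mol_graph` (the anchor).
#' @param direction `"forward"` (raise activity) or `"reverse"`.
#' @param p0,eta,epsilon Overrides of the model configuration.
#' @return A list with `status` (`"selected"`, `"no-candidate"` or
#'   `"invalid-filtered"`), `i_star`, `k_star`, `confidence`, and — when
#'   selected — `optimized` (a `mol_graph`) and `optimized_smiles`.
#' @export
optimize_ligand <- function(model, g, direction = c("forward", "reverse"),
                            p0 = model$config$p0,
                            eta = model$config$eta,
                            epsilon = model$config$epsilon) {
  direction <- match.arg(direction)
  tab <- posterior_tables(model, g, direction, eta = eta, epsilon = epsilon)
  i_star <- select_key_atom(tab, p0)
  if (is.na(i_star)) {
    return(list(status = "no-candidate", i_star = NA_integer_,
                k_star = NA_integer_, confidence = NA_real_))
  }
  k_star <- select_replacement(tab, i_star, p0)
  if (is.na(k_star)) {
    return(list(status = "no-candidate", i_star = i_star,
                k_star = NA_integer_, confidence = NA_real_))
  }
  conf <- tab$P_opt[i_star, k_star]
  if (check_assignment_valid(g, i_star, k_star) != 0) {
    return(list(status = "invalid-filtered", i_star = i_star,
                k_star = k_star, confidence = conf))
  }
  opt_g <- substitute_atom(g, i_star, k_star)
  smi <- tryCatch(to_canonical_smiles(opt_g), error = function(e) NA_character_)
  if (is.na(smi)) {
    return(list(status = "invalid-filtered", i_star = i_star,
                k_star = k_star, confidence = conf))
  }
  list(status = "selected", i_star = i_star, k_star = k_star,
       confidence = conf, optimized = opt_g, optimized_smiles = smi)
}

#' Optimize a table of anchor molecules
#'
#' @param model A trained `cliffopt_model`.
#' @param data Data frame with a `smiles` column (anchors), or a list of
#'   `mol_graph` objects.
#' @param direction `"forward"` or `"reverse"`.
#' @param p0,eta,epsilon Overrides of the model configuration.
#' @return A tibble with one row per anchor: `anchor_smiles`,
#'   `optimized_smiles` (`NA` when nothing was emitted), `atom_index`,
#'   `old_symbol`, `new_symbol`, `confidence`, `status`.
#' @export
optimize_ligands <- function(model, data, direction = c("forward", "reverse"),
                             p0 = model$config$p0,
                             eta = model$config$eta,
                             epsilon = model$config$epsilon) {
  direction <- match.arg(direction)
  graphs <- .as_graph_list(data)
  anchors <- to_canonical_smiles(graphs)
  rows <- lapply(seq_along(graphs), function(m) {
    g <- graphs[[m]]
    res <- optimize_ligand(model, g, direction, p0 = p0, eta = eta,
                           epsilon = epsilon)
    tibble::tibble(
      anchor_smiles = anchors[m],
      optimized_smiles = if (res$status == "selected") res$optimized_smiles else NA_character_,
      atom_index = res$i_star,
      old_symbol = if (!is.na(res$i_star)) g$atoms$symbol[res$i_star] else NA_character_,
      new_symbol = if (!is.na(res$k_star)) .vocab_symbols[res$k_star] else NA_character_,
      confidence = res$confidence,
      status = res$status
    )
  })
  dplyr::bind_rows(rows)
}

#' Uniform random single-substitution baseline
#'
#' For each anchor, draws one (atom, element) pair uniformly at random from
#' all chemically valid non-identity substitutions — the matched-budget
#' baseline against which the guided optimizer is compared.
#'
#' @param data Data frame with a `smiles` column, or list of graphs.
#' @return A tibble with the same schema as [optimize_ligands()].
#' @export
random_substitution_baseline <- function(data) {
  graphs <- .as_graph_list(data)
  anchors <- to_canonical_smiles(graphs)
  rows <- lapply(seq_along(graphs), function(m) {
    g <- graphs[[m]]
    valid <- NULL
    for (i in seq_len(n_atoms(g))) {
      for (k in seq_len(16L)) {
        if (k != g$atoms$symbol_index[i] && check_assignment_valid(g, i, k) == 0) {
          valid <- rbind(valid, c(i, k))
        }
      }
    }
    if (is.null(valid)) {
      return(tibble::tibble(anchor_smiles = anchors[m],
                            optimized_smiles = NA_character_,
                            atom_index = NA_integer_, old_symbol = NA_character_,
                            new_symbol = NA_character_, confidence = NA_real_,
                            status = "no-candidate"))
    }
    pick <- valid[sample.int(nrow(valid), 1), ]
    og <- substitute_atom(g, pick[1], pick[2])
    smi <- tryCatch(to_canonical_smiles(og), error = function(e) NA_character_)
    tibble::tibble(
      anchor_smiles = anchors[m],
      optimized_smiles = smi,
      atom_index = as.integer(pick[1]),
      old_symbol = g$atoms$symbol[pick[1]],
      new_symbol = .vocab_symbols[pick[2]],
      confidence = NA_real_,
      status = if (is.na(smi)) "invalid-filtered" else "selected"
    )
  })
  dplyr::bind_rows(rows)
}
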