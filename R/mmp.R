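# Matched-molecular-pair cliff mining, activity-cliff splits, discovery
# matching and transformation novelty. Two molecules form an MMP here when
# they differ at exactly one atom position (same skeleton, one element
# swapped); an MMP-cliff additionally shows a >= 10-fold activity gap.

# canonical form of the molecule with atom `i` replaced by a dummy; equality
# of masked forms across two molecules certifies a single-atom difference
.masked_canonicals <- function(graphs, positions = NULL) {
  texts <- character(0)
  index <- list()
  for (m in seq_along(graphs)) {
    g <- graphs[[m]]
    pos <- if (is.null(positions)) seq_len(n_atoms(g)) else positions[[m]]
    for (i in pos) {
      gm <- g
      gm$atoms$symbol[i] <- "*"
      gm$atoms$formal_charge[i] <- 0L
      texts <- c(texts, .molfile_text(gm))
      index[[length(index) + 1]] <- c(m, i)
    }
  }
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste(texts, collapse = ""))
  smis <- strsplit(out, "\n", fixed = TRUE)[[1]]
  smis <- trimws(vapply(strsplit(smis, "\t", fixed = TRUE), `[`, character(1), 1))
  idx <- do.call(rbind, index)
  tibble::tibble(mol = idx[, 1], pos = idx[, 2], masked = smis)
}

#' Locate a single-atom difference between two molecules
#'
#' Returns the atom index in `g1` at which the two molecules differ, when
#' they share the same skeleton (same atom count and bonds under some atom
#' relabeling) and differ in element at exactly one position; `NA`
#' otherwise (including when the molecules are identical). The test masks
#' each candidate position with a dummy atom and compares canonical forms.
#'
#' @param g1,g2 `mol_graph` objects.
#' @return Atom index in `g1`, or `NA_integer_`.
#' @examples
#' single_atom_difference(parse_smiles("CCO"), parse_smiles("CCS"))
#' @export
single_atom_difference <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2)) return(NA_integer_)
  if (to_canonical_smiles(g1) == to_canonical_smiles(g2)) return(NA_integer_)
  mc <- .masked_canonicals(list(g1, g2))
  m1 <- mc[mc$mol == 1, ]
  m2 <- mc[mc$mol == 2, ]
  hits <- integer(0)
  for (r in seq_len(nrow(m1))) {
    match2 <- m2$pos[m2$masked == m1$masked[r]]
    for (p2 in match2) {
      if (g1$atoms$symbol[m1$pos[r]] != g2$atoms$symbol[p2]) {
        hits <- c(hits, m1$pos[r])
      }
    }
  }
  if (!length(hits)) return(NA_integer_)
  min(hits)
}

#' Mine MMP-cliffs from a molecule table
#'
#' Finds all unordered pairs of molecules that differ at exactly one atom
#' position and whose activities differ by at least
#' `log10(fold_threshold)` units (>= 10-fold by default). Activities must
#' be on the pActivity (log10) scale.
#'
#' @param data Data frame with columns `smiles` and `activity`.
#' @param fold_threshold Minimum fold change (default 10, i.e. one log
#'   unit).
#' @return A tibble with one row per cliff: `low_smiles`, `high_smiles`,
#'   `low_activity`, `high_activity`, `delta` (high minus low, >= the
#'   threshold), `diff_atom_low`, `low_idx`, `high_idx` (row numbers in
#'   `data`).
#' @export
mine_mmp_cliffs <- function(data, fold_threshold = 10) {
  stopifnot(is.data.frame(data), all(c("smiles", "activity") %in% names(data)))
  if (any(data$activity > 15, na.rm = TRUE)) {
    warning("activities above 15: are these really on a log10 (pActivity) scale?")
  }
  min_delta <- log10(fold_threshold)
  graphs <- parse_smiles(data$smiles)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  canon <- to_canonical_smiles(graphs)
  mc <- .masked_canonicals(graphs)
  mc$symbol <- vapply(seq_len(nrow(mc)),
                      function(r) graphs[[mc$mol[r]]]$atoms$symbol[mc$pos[r]],
                      character(1))
  cliffs <- list()
  seen <- character(0)
  by_mask <- split(seq_len(nrow(mc)), mc$masked)
  for (rows in by_mask) {
    if (length(rows) < 2) next
    for (a in seq_along(rows)) {
      for (b in seq_along(rows)) {
        if (a >= b) next
        r1 <- rows[a]; r2 <- rows[b]
        m1 <- mc$mol[r1]; m2 <- mc$mol[r2]
        if (m1 == m2 || mc$symbol[r1] == mc$symbol[r2]) next
        if (canon[m1] == canon[m2]) next
        delta <- data$activity[m2] - data$activity[m1]
        if (abs(delta) < min_delta || is.na(delta)) next
        lo <- if (delta > 0) m1 else m2
        hi <- if (delta > 0) m2 else m1
        key <- paste(min(lo, hi), max(lo, hi))
        if (key %in% seen) next
        seen <- c(seen, key)
        pos_lo <- if (delta > 0) mc$pos[r1] else mc$pos[r2]
        cliffs[[length(cliffs) + 1]] <- tibble::tibble(
          low_smiles = canon[lo], high_smiles = canon[hi],
          low_activity = data$activity[lo], high_activity = data$activity[hi],
          delta = abs(delta), diff_atom_low = pos_lo,
          low_idx = lo, high_idx = hi
        )
      }
    }
  }
  if (!length(cliffs)) {
    return(tibble::tibble(low_smiles = character(0), high_smiles = character(0),
                          low_activity = numeric(0), high_activity = numeric(0),
                          delta = numeric(0), diff_atom_low = integer(0),
                          low_idx = integer(0), high_idx = integer(0)))
  }
  out <- dplyr::bind_rows(cliffs)
  dplyr::arrange(out, .data$low_idx, .data$high_idx)
}

#' Activity-cliff train/held-out splits
#'
#' In `"optimization"` mode the training set keeps every non-cliff molecule
#' plus the low-activity side of each cliff, and the high sides are held
#' out as optimization targets; `"reverse"` mode mirrors this (highs train,
#' lows held out).
#'
#' @param data Data frame with `smiles` and `activity`.
#' @param cliffs Output of [mine_mmp_cliffs()] on `data`.
#' @param mode `"optimization"` or `"reverse"`.
#' @return A list with tibbles `train` and `heldout` (columns `smiles`,
#'   `activity`); their canonical SMILES sets are disjoint.
#' @export
make_ac_splits <- function(data, cliffs, mode = c("optimization", "reverse")) {
  mode <- match.arg(mode)
  graphs <- parse_smiles(data$smiles)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  canon <- to_canonical_smiles(graphs)
  keep_idx <- if (mode == "optimization") cliffs$low_idx else cliffs$high_idx
  hold_idx <- if (mode == "optimization") cliffs$high_idx else cliffs$low_idx
  in_cliff <- union(cliffs$low_idx, cliffs$high_idx)
  train_rows <- sort(union(setdiff(seq_len(nrow(data)), in_cliff), keep_idx))
  train_canon <- unique(canon[train_rows])
  hold_rows <- sort(setdiff(hold_idx, train_rows))
  hold_rows <- hold_rows[!canon[hold_rows] %in% train_canon]
  dedup <- function(rows) rows[!duplicated(canon[rows])]
  train_rows <- dedup(train_rows); hold_rows <- dedup(hold_rows)
  list(
    train = tibble::tibble(smiles = canon[train_rows],
                           activity = data$activity[train_rows]),
    heldout = tibble::tibble(smiles = canon[hold_rows],
                             activity = data$activity[hold_rows])
  )
}

#' Match generated molecules against held-out targets
#'
#' Exact canonical-SMILES matching of optimizer output against the held-out
#' side of the cliffs; a match means the optimizer rediscovered a known
#' molecule it never saw in training.
#'
#' @param generated Character vector of SMILES, or a results tibble with an
#'   `optimized_smiles` column.
#' @param heldout_targets Character vector of SMILES, or a tibble with a
#'   `smiles` column.
#' @return A list with `matched` (tibble `generated`, `target`) and `n`.
#' @export
match_discovered <- function(generated, heldout_targets) {
  gen <- if (is.data.frame(generated)) generated$optimized_smiles else generated
  tgt <- if (is.data.frame(heldout_targets)) heldout_targets$smiles else heldout_targets
  gen <- gen[!is.na(gen)]
  if (!length(gen) || !length(tgt)) {
    return(list(matched = tibble::tibble(generated = character(0),
                                         target = character(0)), n = 0L))
  }
  gen_c <- to_canonical_smiles(parse_smiles(gen))
  if (length(gen) == 1) gen_c <- gen_c[1]
  tgt_c <- to_canonical_smiles(parse_smiles(tgt))
  if (length(tgt) == 1) tgt_c <- tgt_c[1]
  hits <- which(gen_c %in% tgt_c)
  matched <- tibble::tibble(
    generated = gen_c[hits],
    target = gen_c[hits]
  )
  matched <- matched[!duplicated(matched$generated), , drop = FALSE]
  list(matched = matched, n = nrow(matched))
}

#' Local transformation key of a single-atom edit
#'
#' A deterministic fingerprint of "what changed and in what local context":
#' the canonical form of the substituted atom's first bonding shell (the
#' atom masked as a dummy, its neighbors and the connecting bonds) together
#' with the old and new element symbols.
#'
#' @param g Anchor `mol_graph`.
#' @param i Substituted atom index.
#' @param new_symbol Replacement element symbol.
#' @return Character scalar.
#' @export
transformation_key <- function(g, i, new_symbol) {
  nb <- g$adj[[i]]
  sel <- c(i, nb)
  remap <- match(seq_len(n_atoms(g)), sel)
  keep <- g$bonds[g$bonds$i == i | g$bonds$j == i, , drop = FALSE]
  atoms <- g$atoms[sel, , drop = FALSE]
  atoms$symbol[1] <- "*"
  atoms$formal_charge <- 0L
  star <- list(atoms = atoms,
               bonds = tibble::tibble(i = remap[keep$i], j = remap[keep$j],
                                      order = keep$order))
  ctx <- tryCatch({
    txt <- .molfile_text(list(n_atoms = nrow(atoms), atoms = atoms,
                              bonds = star$bonds))
    out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
    trimws(strsplit(out, "[\t\n]")[[1]][1])
  }, error = function(e) paste(sort(atoms$symbol[-1]), collapse = ""))
  paste0(ctx, "|", g$atoms$symbol[i], ">", new_symbol)
}

#' Evaluation report for an optimization run
#'
#' Counts anchors, generated and discovered molecules, summarizes the
#' model's predicted activity over the generated set, and counts novel
#' transformations (local-edit keys absent from the training cliffs).
#'
#' @param results Tibble from [optimize_ligands()].
#' @param heldout Held-out targets (tibble with `smiles` or character).
#' @param model Optional `cliffopt_model` for predicted-activity summaries.
#' @param train_cliffs Optional training-set cliff tibble from
#'   [mine_mmp_cliffs()] for novelty counting.
#' @return One-row tibble: `n_anchor`, `n_generated`, `n_discovered`,
#'   `max_pred`, `mean_pred`, `novel_transformations`.
#' @export
evaluate_optimization <- function(results, heldout, model = NULL,
                                  train_cliffs = NULL) {
  n_anchor <- nrow(results)
  gen <- results$optimized_smiles[!is.na(results$optimized_smiles)]
  n_generated <- length(gen)
  disc <- match_discovered(results, heldout)
  n_discovered <- disc$n
  stopifnot(n_discovered <= n_generated, n_generated <= n_anchor)
  max_pred <- mean_pred <- NA_real_
  if (!is.null(model) && n_generated > 0) {
    preds <- stats::predict(model, tibble::tibble(smiles = gen))
    col <- if (model$config$task == "classification") preds$.logit else preds$.pred
    max_pred <- max(col); mean_pred <- mean(col)
  }
  novel <- NA_integer_
  if (!is.null(train_cliffs) && n_discovered > 0) {
    train_keys <- .cliff_keys(train_cliffs)
    disc_rows <- results[!is.na(results$optimized_smiles), , drop = FALSE]
    gen_c <- to_canonical_smiles(parse_smiles(disc_rows$optimized_smiles))
    disc_rows <- disc_rows[gen_c %in% disc$matched$generated, , drop = FALSE]
    keys <- vapply(seq_len(nrow(disc_rows)), function(r) {
      g <- parse_smiles(disc_rows$anchor_smiles[r])
      transformation_key(g, disc_rows$atom_index[r], disc_rows$new_symbol[r])
    }, character(1))
    novel <- sum(!keys %in% train_keys)
  }
  tibble::tibble(n_anchor = n_anchor, n_generated = n_generated,
                 n_discovered = n_discovered, max_pred = max_pred,
                 mean_pred = mean_pred, novel_transformations = novel)
}

.cliff_keys <- function(cliffs) {
  if (!nrow(cliffs)) return(character(0))
  vapply(seq_len(nrow(cliffs)), function(r) {
    g_lo <- parse_smiles(cliffs$low_smiles[r])
    g_hi <- parse_smiles(cliffs$high_smiles[r])
    i <- cliffs$diff_atom_low[r]
    # the high molecule's symbol at the matched position: recover via the
    # masked-form match
    j <- single_atom_difference(g_hi, g_lo)
    new_sym <- if (!is.na(j)) g_hi$atoms$symbol[j] else "?"
    transformation_key(g_lo, i, new_sym)
  }, character(1))
}
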