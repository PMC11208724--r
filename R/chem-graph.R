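# Molecular graphs: parsing, canonicalization, featurization, substitution.
# SMILES interpretation and canonicalization are delegated to OpenBabel
# (through ChemmineOB); this file only moves between OpenBabel's V2000
# molfile text and the package's heavy-atom graph representation.

#' Construct a molecular graph object
#'
#' Low-level constructor; most users should call [parse_smiles()] instead.
#'
#' @param atoms Tibble with columns `symbol`, `symbol_index`, `formal_charge`,
#'   `explicit_valence`, `implicit_h`, `is_aromatic`.
#' @param bonds Tibble with columns `i`, `j`, `order` (one of
#'   `"single"`, `"double"`, `"triple"`, `"aromatic"`), `in_ring`,
#'   `conjugated`.
#' @return An object of class `mol_graph`.
#' @keywords internal
#' @export
new_mol_graph <- function(atoms, bonds) {
  n <- nrow(atoms)
  stopifnot(n >= 1)
  if (nrow(bonds) > 0) {
    stopifnot(all(bonds$i >= 1), all(bonds$i <= n),
              all(bonds$j >= 1), all(bonds$j <= n),
              all(bonds$i != bonds$j))
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between an atom pair")
  }
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds$i[b]]] <- c(adj[[bonds$i[b]]], bonds$j[b])
    adj[[bonds$j[b]]] <- c(adj[[bonds$j[b]]], bonds$i[b])
  }
  adj <- lapply(adj, function(x) sort(unique(as.integer(x))))
  g <- structure(
    list(atoms = atoms, bonds = bonds, adj = adj, n_atoms = n),
    class = "mol_graph"
  )
  if (n > 1 && length(.components(g)) > 1) {
    stop("multi-fragment molecule: inputs must be a single connected fragment")
  }
  g
}

.components <- function(g) {
  n <- g$n_atoms
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in g$adj[[v]]) if (is.na(comp[w])) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  split(seq_len(n), comp)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph: %d atoms, %d bonds> %s\n",
              x$n_atoms, nrow(x$bonds),
              paste(x$atoms$symbol, collapse = "")))
  invisible(x)
}

#' Number of heavy atoms
#' @param g A `mol_graph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) g$n_atoms

.bond_order_value <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# ---- V2000 molfile text <-> graph -------------------------------------------

# Parse the atom/bond/charge blocks of one V2000 molfile produced by
# OpenBabel. ChemmineR's reader mishandles single-atom molecules, hence this
# minimal fixed-format reader (the chemistry itself is still OpenBabel's).
.read_molfile <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1) return(NULL)
  atom_lines <- lines[4 + seq_len(na)]
  symbols <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      code = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(i = integer(0), j = integer(0), code = integer(0))
  }
  charges <- rep(0L, na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    nset <- toks[1]
    for (q in seq_len(nset)) {
      charges[toks[2 * q]] <- toks[2 * q + 1]
    }
  }
  list(symbols = symbols, bonds = bonds, charges = charges, title = trimws(lines[1]))
}

.split_sdf_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\${4}", lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  mapply(function(s, e) lines[s:(e - 1)], starts, ends, SIMPLIFY = FALSE)
}

.molfile_text <- function(g) {
  nb <- nrow(g$bonds)
  order_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
  out <- c(
    "cliffopt", "  cliffopt", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", g$n_atoms, nb),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            g$atoms$symbol),
    if (nb > 0) sprintf("%3d%3d%3d  0  0  0  0", g$bonds$i, g$bonds$j,
                        order_code[g$bonds$order])
  )
  chg <- which(g$atoms$formal_charge != 0)
  if (length(chg)) {
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                         paste0(sprintf("%4d%4d", chg, g$atoms$formal_charge[chg]),
                                collapse = "")))
  }
  paste(c(out, "M  END", "$$$$", ""), collapse = "\n")
}

# ---- parsing ----------------------------------------------------------------

#' Parse SMILES into molecular graphs
#'
#' Interprets SMILES with OpenBabel, records the heavy-atom graph with
#' implicit hydrogen counts, and perceives rings and aromaticity. Stereo
#' annotations are dropped. Only single-fragment molecules whose heavy atoms
#' all lie in the 16-symbol vocabulary (see [element_vocabulary()]) are
#' accepted.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A single `mol_graph` if `smiles` has length 1, otherwise a list of
#'   `mol_graph` objects (named after `names(smiles)` when present).
#' @examples
#' g <- parse_smiles("CCO")
#' n_atoms(g)
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  tagged <- paste0(smiles, " cliffopt_id_", seq_along(smiles))
  input <- paste0(paste(tagged, collapse = "\n"), "\n")
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", input)
  sdfh <- ChemmineOB::convertFormat("SMI", "SDF", input,
                                    options = data.frame(names = "h", args = ""))
  blocks <- .split_sdf_blocks(sdf)
  blocks_h <- .split_sdf_blocks(sdfh)
  parsed <- lapply(blocks, .read_molfile)
  parsed_h <- lapply(blocks_h, .read_molfile)
  by_id <- function(lst) {
    ids <- vapply(lst, function(p) {
      if (is.null(p)) NA_character_ else sub("^.*cliffopt_id_", "", p$title)
    }, character(1))
    stats::setNames(lst, ids)
  }
  parsed <- by_id(parsed)
  parsed_h <- by_id(parsed_h)
  out <- vector("list", length(smiles))
  for (m in seq_along(smiles)) {
    id <- as.character(m)
    p <- parsed[[id]]
    if (is.null(p)) stop(sprintf("unparseable SMILES: '%s'", smiles[m]))
    ph <- parsed_h[[id]]
    out[[m]] <- .graph_from_parsed(p, ph, smiles[m])
  }
  if (!is.null(names(smiles))) names(out) <- names(smiles)
  if (length(out) == 1) out[[1]] else out
}

.graph_from_parsed <- function(p, ph, smi) {
  symbols <- p$symbols
  bad <- setdiff(unique(symbols), .vocab_symbols)
  if (length(bad)) {
    stop(sprintf("unsupported element: %s (in '%s')",
                 paste(bad, collapse = ", "), smi))
  }
  n <- length(symbols)
  # implicit hydrogens: count explicit H neighbors in the H-added parse
  # (OpenBabel appends hydrogens after the heavy atoms, preserving order)
  implicit_h <- rep(0L, n)
  if (!is.null(ph)) {
    h_idx <- which(ph$symbols == "H")
    if (length(h_idx)) {
      hb <- ph$bonds
      for (r in seq_len(nrow(hb))) {
        if (hb$i[r] %in% h_idx && hb$j[r] <= n) {
          implicit_h[hb$j[r]] <- implicit_h[hb$j[r]] + 1L
        } else if (hb$j[r] %in% h_idx && hb$i[r] <= n) {
          implicit_h[hb$i[r]] <- implicit_h[hb$i[r]] + 1L
        }
      }
    }
  }
  bonds <- p$bonds
  order <- c("single", "double", "triple", "aromatic")[pmin(bonds$code, 4L)]
  bonds_tb <- tibble::tibble(
    i = bonds$i, j = bonds$j, order = order,
    in_ring = FALSE, conjugated = FALSE
  )
  arom_atom <- rep(FALSE, n)
  if (n > 1 && nrow(bonds_tb) > 0) {
    ring_info <- .perceive_rings(p, n)
    bonds_tb$in_ring <- ring_info$bond_in_ring(bonds_tb)
    arom_atom <- ring_info$aromatic_atoms
    arom_bond <- ring_info$aromatic_bond(bonds_tb)
    bonds_tb$order[arom_bond] <- "aromatic"
  }
  ev <- rep(0, n)
  for (r in seq_len(nrow(bonds_tb))) {
    v <- .bond_order_value[[bonds_tb$order[r]]]
    ev[bonds_tb$i[r]] <- ev[bonds_tb$i[r]] + v
    ev[bonds_tb$j[r]] <- ev[bonds_tb$j[r]] + v
  }
  # a bond is treated as conjugated when aromatic, or when both endpoints
  # carry some multiple bond (simple surrogate for pi-system membership)
  has_multi <- rep(FALSE, n)
  for (r in seq_len(nrow(bonds_tb))) {
    if (bonds_tb$order[r] != "single") {
      has_multi[bonds_tb$i[r]] <- TRUE
      has_multi[bonds_tb$j[r]] <- TRUE
    }
  }
  bonds_tb$conjugated <- bonds_tb$order == "aromatic" |
    (has_multi[bonds_tb$i] & has_multi[bonds_tb$j])
  atoms <- tibble::tibble(
    symbol = symbols,
    symbol_index = .symbol_index(symbols),
    formal_charge = as.integer(p$charges),
    explicit_valence = ev,
    implicit_h = implicit_h,
    is_aromatic = arom_atom
  )
  new_mol_graph(atoms, bonds_tb)
}

# ring membership and aromaticity via ChemmineR's perception on the same
# molfile text OpenBabel produced
.perceive_rings <- function(p, n) {
  empty <- list(
    aromatic_atoms = rep(FALSE, n),
    bond_in_ring = function(b) rep(FALSE, nrow(b)),
    aromatic_bond = function(b) rep(FALSE, nrow(b))
  )
  g_adj <- vector("list", n)
  for (r in seq_len(nrow(p$bonds))) {
    g_adj[[p$bonds$i[r]]] <- c(g_adj[[p$bonds$i[r]]], p$bonds$j[r])
    g_adj[[p$bonds$j[r]]] <- c(g_adj[[p$bonds$j[r]]], p$bonds$i[r])
  }
  sdf_txt <- paste(
    c("m", "  x", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(p$bonds)),
      sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              p$symbols),
      sprintf("%3d%3d%3d  0  0  0  0", p$bonds$i, p$bonds$j, p$bonds$code),
      "M  END", "$$$$"), collapse = "\n")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(strsplit(sdf_txt, "\n")[[1]]))
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdfset[[1]], upper = 20,
                                      type = "all", arom = TRUE)),
    error = function(e) NULL
  )
  if (is.null(rr) || length(rr$RINGS) == 0) return(empty)
  ring_atoms <- lapply(rr$RINGS, function(x) as.integer(sub("^.*_", "", x)))
  aromatic <- rr$AROMATIC
  arom_atoms <- rep(FALSE, n)
  ring_pairs <- character(0)
  arom_pairs <- character(0)
  for (q in seq_along(ring_atoms)) {
    ra <- ring_atoms[[q]]
    prs <- paste(pmin(ra, c(ra[-1], ra[1])), pmax(ra, c(ra[-1], ra[1])))
    ring_pairs <- c(ring_pairs, prs)
    if (isTRUE(aromatic[q])) {
      arom_atoms[ra] <- TRUE
      arom_pairs <- c(arom_pairs, prs)
    }
  }
  list(
    aromatic_atoms = arom_atoms,
    bond_in_ring = function(b) paste(pmin(b$i, b$j), pmax(b$i, b$j)) %in% ring_pairs,
    aromatic_bond = function(b) paste(pmin(b$i, b$j), pmax(b$i, b$j)) %in% arom_pairs
  )
}

# ---- canonical SMILES -------------------------------------------------------

#' Canonical SMILES for a molecular graph
#'
#' Serializes the graph to molfile text and asks OpenBabel for the canonical
#' SMILES, so two graphs receive the same string exactly when they are the
#' same molecule up to atom relabeling.
#'
#' @param g A `mol_graph` or a list of them.
#' @return Character vector of canonical SMILES.
#' @examples
#' to_canonical_smiles(parse_smiles("OCC")) == to_canonical_smiles(parse_smiles("CCO"))
#' @export
to_canonical_smiles <- function(g) {
  graphs <- if (inherits(g, "mol_graph")) list(g) else g
  txt <- paste(vapply(graphs, .molfile_text, character(1)), collapse = "")
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  smis <- strsplit(out, "\n", fixed = TRUE)[[1]]
  smis <- vapply(strsplit(smis, "\t", fixed = TRUE), `[`, character(1), 1)
  smis <- trimws(smis)
  if (length(smis) != length(graphs) || any(!nzchar(smis))) {
    stop("unsanitizable molecule: canonicalization failed")
  }
  smis
}

# ---- featurization ----------------------------------------------------------

#' Chemical feature matrices for a molecule
#'
#' Atom rows are `[16-way one-hot symbol | degree one-hot 0-5 | formal
#' charge | aromatic flag | implicit-H one-hot 0-4]` (29 columns). Bond rows
#' are `[order one-hot (single, double, triple, aromatic) | conjugated |
#' in-ring]` (6 columns), one row per undirected bond in the order they are
#' stored in the graph.
#'
#' @param g A `mol_graph`.
#' @return A list with elements `atoms` (`N_a x 29` matrix) and
#'   `bonds` (`|bonds| x 6` matrix).
#' @export
featurize <- function(g) {
  n <- g$n_atoms
  A <- matrix(0, n, 29)
  for (i in seq_len(n)) {
    A[i, g$atoms$symbol_index[i]] <- 1
    deg <- min(length(g$adj[[i]]), 5L)
    A[i, 17 + deg] <- 1
    A[i, 23] <- g$atoms$formal_charge[i]
    A[i, 24] <- as.numeric(g$atoms$is_aromatic[i])
    hh <- min(max(g$atoms$implicit_h[i], 0L), 4L)
    A[i, 25 + hh] <- 1
  }
  nb <- nrow(g$bonds)
  B <- matrix(0, nb, 6)
  if (nb > 0) {
    ord <- match(g$bonds$order, c("single", "double", "triple", "aromatic"))
    for (b in seq_len(nb)) B[b, ord[b]] <- 1
    B[, 5] <- as.numeric(g$bonds$conjugated)
    B[, 6] <- as.numeric(g$bonds$in_ring)
  }
  list(atoms = A, bonds = B)
}

# ---- substitution -----------------------------------------------------------

#' Validity mask for a single-atom element assignment
#'
#' Checks whether placing element `k` at atom position `i`, keeping every
#' bond, would violate bonding capacity. Follows the convention of the mask
#' function in the validity objective: returns `1` for an *invalid*
#' assignment and `0` for a valid one.
#'
#' Rules: the identity assignment is always valid; the `"other"` class is
#' never a valid target; aromatic positions accept only aromatic-capable
#' elements; otherwise the assignment is invalid when
#' `ceil(explicit_valence) + |formal_charge| > max_valence(k)` (aromatic
#' bonds count 1.5 toward the explicit valence, rounded up — a deliberately
#' conservative check).
#'
#' @param g A `mol_graph`.
#' @param i Atom index.
#' @param k Symbol index in 1..16.
#' @return `0` (valid) or `1` (invalid).
#' @export
check_assignment_valid <- function(g, i, k) {
  stopifnot(i >= 1, i <= g$n_atoms, k >= 1, k <= 16)
  if (k == g$atoms$symbol_index[i]) return(0)
  if (.vocab_symbols[k] == "other") return(1)
  if (g$atoms$is_aromatic[i] && !.vocab_aromatic_ok[[k]]) return(1)
  need <- ceiling(g$atoms$explicit_valence[i]) + abs(g$atoms$formal_charge[i])
  if (need > .vocab_max_valence[[k]]) return(1)
  0
}

#' Replace the element of one atom
#'
#' Returns a new graph identical to `g` except that atom `i` carries element
#' `k`; bonds are untouched and the implicit hydrogen count is recomputed
#' from the new element's typical valence. The assignment must pass
#' [check_assignment_valid()].
#'
#' @inheritParams check_assignment_valid
#' @return A `mol_graph`.
#' @examples
#' g <- parse_smiles("CCO")
#' s <- substitute_atom(g, 3, 8)  # O -> S
#' to_canonical_smiles(s)
#' @export
substitute_atom <- function(g, i, k) {
  if (check_assignment_valid(g, i, k) != 0) {
    stop(sprintf("valence violation: cannot place %s at atom %d",
                 .vocab_symbols[k], i))
  }
  atoms <- g$atoms
  if (k == atoms$symbol_index[i]) return(g)
  atoms$symbol[i] <- .vocab_symbols[k]
  atoms$symbol_index[i] <- as.integer(k)
  atoms$implicit_h[i] <- max(0L, as.integer(
    .vocab_default_valence[[k]] - ceiling(atoms$explicit_valence[i])
  ))
  new_mol_graph(atoms, g$bonds)
}

# ---- tabular I/O ------------------------------------------------------------

#' Read a molecule table from CSV
#'
#' Expects a header with a `smiles` column and (optionally) one activity
#' column on the pActivity scale for regression or 0/1 for classification.
#'
#' @param path CSV file path.
#' @param activity_col Name of the activity column; defaults to the first
#'   non-smiles column when present.
#' @return A tibble with columns `smiles` and (if found) `activity`.
#' @export
read_molecule_csv <- function(path, activity_col = NULL) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"smiles" %in% names(df)) stop("CSV must contain a 'smiles' column")
  out <- tibble::tibble(smiles = as.character(df$smiles))
  if (is.null(activity_col)) {
    cand <- setdiff(names(df), "smiles")
    if (length(cand)) activity_col <- cand[[1]]
  }
  if (!is.null(activity_col)) {
    if (!activity_col %in% names(df)) {
      stop(sprintf("activity column '%s' not in CSV", activity_col))
    }
    out$activity <- as.numeric(df[[activity_col]])
  }
  out
}

#' Read molecules from an SDF file (connectivity only)
#'
#' @param path SDF file path.
#' @return A tibble with a `smiles` column of canonical SMILES.
#' @export
read_molecule_sdf <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  smis <- ChemmineOB::convertFormat("SDF", "CAN", paste0(txt, "\n"))
  smis <- strsplit(smis, "\n", fixed = TRUE)[[1]]
  smis <- trimws(vapply(strsplit(smis, "\t", fixed = TRUE), `[`, character(1), 1))
  tibble::tibble(smiles = smis[nzchar(smis)])
}

#' Write an optimization results table to CSV
#'
#' @param results Tibble as returned by [optimize_ligands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
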