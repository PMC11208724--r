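# Synthetic scaffold libraries with a planted element-at-site activity
# rule. Each scaffold is a small alkyl chain or carbocycle with one marked
# substitution site; emitting one variant per allowed site element yields
# true matched molecular pairs, and an effect gap >= 1 log unit between two
# site elements plants genuine MMP-cliffs whose identity is known exactly.

#' Configuration of the synthetic fixture generator
#'
#' Defaults define the package's standard study conditions: 60 paired
#' scaffolds plus 80 single-variant background scaffolds (200 molecules),
#' two site elements (O at offset 0, S at offset +2 log units — a planted
#' 100-fold activity cliff per scaffold), scaffold base activities uniform
#' in 5..7 pActivity units, and Gaussian assay noise of 0.2 log units
#' (small against the 2-unit planted gap, nonzero to avoid degenerate
#' fits).
#'
#' @param n_scaffolds Number of paired scaffolds (one variant per site
#'   element each; these carry the planted cliffs).
#' @param n_background Number of additional single-variant scaffolds. Real
#'   screening libraries are dominated by non-cliff ligands; background
#'   scaffolds emulate that and, under activity-cliff splits, keep every
#'   site element represented in training.
#' @param site_elements Element symbols allowed at the marked site (one
#'   variant is emitted per element per scaffold).
#' @param effects Named numeric: activity offset (log10 units) per site
#'   element; must include every site element and contain at least one
#'   pair with a gap >= 1 so cliffs exist by construction.
#' @param base_range Interval for the per-scaffold base activity.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; the fixture is fully deterministic given it.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_scaffolds = 60,
                           n_background = 80,
                           site_elements = c("O", "S"),
                           effects = c(O = 0, S = 2),
                           base_range = c(5, 7),
                           noise_sigma = 0.2,
                           seed = 1L) {
  stopifnot(length(site_elements) >= 2,
            all(site_elements %in% names(effects)),
            noise_sigma >= 0, length(base_range) == 2)
  eff <- effects[site_elements]
  gaps <- abs(outer(eff, eff, "-"))
  if (max(gaps) < 1) stop("site-element effect gap must reach 1 log unit")
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 n_background = as.integer(n_background),
                 site_elements = site_elements, effects = effects,
                 base_range = base_range, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# SMILES token for a pendant site atom bonded once
.site_token <- function(sym) {
  organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
  if (sym %in% organic) return(sym)
  h <- max(.vocab_default_valence[[sym]] - 1, 0)
  if (h > 0) sprintf("[%sH%d]", sym, h) else sprintf("[%s]", sym)
}

# one random scaffold: backbone spec + site position; returns a function of
# the site element producing SMILES
.sample_scaffold <- function() {
  n <- sample(4:10, 1)
  ring <- n >= 5 && stats::runif(1) < 0.5
  n_dec <- sample(0:2, 1)
  attachable <- if (ring) seq_len(n - 1) else seq_len(n)
  site_pos <- sample(attachable, 1)
  dec_pos <- integer(0)
  open <- setdiff(attachable, integer(0))
  for (q in seq_len(n_dec)) {
    cand <- setdiff(open, dec_pos)  # at most one decoration per atom
    if (!length(cand)) break
    dec_pos <- c(dec_pos, if (length(cand) == 1) cand else sample(cand, 1))
  }
  function(site_sym) {
    tokens <- rep("C", n)
    if (ring) { tokens[1] <- "C1"; tokens[n] <- "C1" }
    branches <- rep("", n)
    for (p in dec_pos) branches[p] <- paste0(branches[p], "(C)")
    branches[site_pos] <- paste0(branches[site_pos],
                                 "(", .site_token(site_sym), ")")
    paste0(tokens, branches, collapse = "")
  }
}

#' Generate a regression fixture with planted MMP-cliffs
#'
#' For each scaffold one molecule per site element is emitted, with
#' `activity = base(scaffold) + effect(element) + N(0, noise_sigma)`.
#' Scaffolds are deduplicated on the canonical form of the site-masked
#' skeleton, which guarantees that the only single-atom-difference pairs
#' in the library are the planted same-scaffold ones.
#'
#' @param cfg A [fixture_config()].
#' @return A list with `data` (tibble `smiles`, `activity`, `scaffold`,
#'   `site_element`) and `truth` (tibble of planted cliffs: `low_smiles`,
#'   `high_smiles`, `low_activity`, `high_activity`, `delta`, `scaffold`).
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  set.seed(cfg$seed)
  seen_skeleton <- character(0)
  rows <- list()
  truth <- list()
  n_total <- cfg$n_scaffolds + (cfg$n_background %||% 0L)
  for (sc in seq_len(n_total)) {
    paired <- sc <= cfg$n_scaffolds
    elements <- if (paired) cfg$site_elements else {
      cfg$site_elements[(sc - cfg$n_scaffolds - 1) %% length(cfg$site_elements) + 1]
    }
    ok <- FALSE
    for (try in 1:50) {
      maker <- .sample_scaffold()
      smis <- vapply(elements, function(e) maker(e), character(1))
      graphs <- tryCatch({
        g <- parse_smiles(unname(smis))
        if (inherits(g, "mol_graph")) list(g) else g
      }, error = function(e) NULL)
      if (is.null(graphs)) next
      canon <- tryCatch(to_canonical_smiles(graphs), error = function(e) NULL)
      if (is.null(canon) || anyDuplicated(canon)) next
      # skeleton key: first variant with its site atom (the only non-carbon
      # atom) masked; guards against cross-scaffold matched pairs
      site_i <- which(graphs[[1]]$atoms$symbol != "C")
      if (length(site_i) != 1) next
      skel <- .masked_canonicals(graphs[1], positions = list(site_i))$masked
      if (skel %in% seen_skeleton) next
      seen_skeleton <- c(seen_skeleton, skel)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not sample a fresh valid scaffold; enlarge the grammar")
    base <- stats::runif(1, cfg$base_range[1], cfg$base_range[2])
    act <- base + cfg$effects[elements] +
      stats::rnorm(length(elements), 0, cfg$noise_sigma)
    rows[[sc]] <- tibble::tibble(
      smiles = canon, activity = unname(act), scaffold = sc,
      site_element = elements
    )
    if (!paired) next
    eff <- cfg$effects[elements]
    for (a in seq_along(elements)) {
      for (b in seq_along(elements)) {
        if (a == b || eff[a] >= eff[b]) next
        if (abs(eff[b] - eff[a]) >= 1) {
          truth[[length(truth) + 1]] <- tibble::tibble(
            low_smiles = canon[a], high_smiles = canon[b],
            low_activity = act[a], high_activity = act[b],
            delta = abs(eff[b] - eff[a]), scaffold = sc
          )
        }
      }
    }
  }
  list(data = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
}

#' Generate a binary classification fixture
#'
#' Same library as [generate_fixture()], with labels thresholded at the
#' median of the generated activities (label 1 = active), so label balance
#' is close to 50/50 by construction.
#'
#' @param cfg A [fixture_config()].
#' @return A list with `data` (tibble `smiles`, `activity` in 0/1,
#'   `pactivity`, `scaffold`, `site_element`) and `truth` as in
#'   [generate_fixture()].
#' @export
generate_classification_fixture <- function(cfg = fixture_config()) {
  fx <- generate_fixture(cfg)
  thr <- stats::median(fx$data$activity)
  fx$data$pactivity <- fx$data$activity
  fx$data$activity <- as.integer(fx$data$pactivity >= thr)
  fx$threshold <- thr
  fx
}
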