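#' The 16-element vocabulary
#'
#' The atom-symbol vocabulary used throughout the package: 15 concrete
#' elements common in drug-like ligands plus a catch-all `"other"` class.
#' Every atom of every molecule handled by the package is mapped onto one of
#' these 16 symbol indices, and the decoder's per-atom output is a
#' probability distribution over exactly these 16 classes.
#'
#' `max_valence` is the maximum bonding capacity used by the substitution
#' validity check ([check_assignment_valid()]); `default_valence` is the
#' typical neutral-atom valence used to recompute implicit hydrogen counts
#' after a substitution; `aromatic_ok` marks elements that can sit on an
#' aromatic ring position and is used to restrict substitutions at aromatic
#' sites to chemically sensible targets.
#'
#' @return A tibble with columns `index`, `symbol`, `max_valence`,
#'   `default_valence`, `aromatic_ok`.
#' @examples
#' element_vocabulary()
#' @export
element_vocabulary <- function() {
  tibble::tibble(
    index = 1:16,
    symbol = .vocab_symbols,
    max_valence = unname(.vocab_max_valence),
    default_valence = unname(.vocab_default_valence),
    aromatic_ok = unname(.vocab_aromatic_ok)
  )
}

.vocab_symbols <- c("B", "C", "N", "O", "F", "Si", "P", "S",
                    "Cl", "As", "Se", "Br", "Te", "I", "At", "other")

.vocab_max_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5,
                        S = 6, Cl = 1, As = 5, Se = 6, Br = 1, Te = 6,
                        I = 1, At = 1, other = 4)

# typical neutral valence, used only to recompute implicit hydrogens
.vocab_default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                            S = 2, Cl = 1, As = 3, Se = 2, Br = 1, Te = 2,
                            I = 1, At = 1, other = 0)

# elements accepted as substitution targets on aromatic ring positions
.vocab_aromatic_ok <- c(B = TRUE, C = TRUE, N = TRUE, O = FALSE, F = FALSE,
                        Si = FALSE, P = TRUE, S = FALSE, Cl = FALSE,
                        As = TRUE, Se = FALSE, Br = FALSE, Te = FALSE,
                        I = FALSE, At = FALSE, other = FALSE)

.symbol_index <- function(symbol) {
  idx <- match(symbol, .vocab_symbols)
  idx[is.na(idx)] <- NA_integer_
  idx
}

#' Hash of the element vocabulary
#'
#' A short content fingerprint of the symbol/valence tables, recorded in
#' model checkpoints and run manifests so that a model is never applied under
#' a different vocabulary than it was trained with.
#'
#' @return A character scalar.
#' @export
vocabulary_hash <- function() {
  v <- element_vocabulary()
  txt <- paste(v$symbol, v$max_valence, v$default_valence, collapse = ";")
  .text_hash(txt)
}

# small deterministic polynomial hash; no external digest dependency
.text_hash <- function(txt) {
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% 68719476731
  format(h, scientific = FALSE)
}
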