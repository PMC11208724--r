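# brute-force enumeration oracle for the maximum-posterior selection:
# scan all admissible (i, k) pairs for the key atom, then the candidate
# row for the replacement, mirroring the definitions rather than the
# implementation
brute_select <- function(tab, p0) {
  n <- nrow(tab$P_opt)
  best_val <- -Inf
  i_star <- NA_integer_
  for (i in seq_len(n)) {
    for (k in 1:16) {
      if (tab$P_recon[i, k] >= p0) next  # confusable
      v <- tab$P_opt[i, k]
      if (v > best_val + 1e-15) { best_val <- v; i_star <- i }
    }
  }
  if (is.na(i_star)) return(list(i = NA_integer_, k = NA_integer_))
  kb <- NA_integer_; kv <- -Inf
  for (k in 1:16) {
    if (k == tab$sym[i_star]) next
    if (tab$P_opt[i_star, k] < p0) next
    if (tab$P_opt[i_star, k] > kv + 1e-15) { kv <- tab$P_opt[i_star, k]; kb <- k }
  }
  list(i = i_star, k = kb)
}

rand_table <- function(n, quantize = FALSE) {
  mk <- function() {
    p <- matrix(stats::rexp(n * 16), n, 16)
    if (quantize) p <- round(p, 1) + 0.01  # force frequent exact ties
    p / rowSums(p)
  }
  list(P_recon = mk(), P_opt = mk(), sym = sample(16, n, replace = TRUE))
}

test_that("confusable sets follow the threshold rule", {
  P <- matrix(1 / 16, 2, 16)
  P[1, 4] <- 0.9; P[1, -4] <- 0.1 / 15
  expect_equal(confusable_set(P, 1, 0.5), 4)
  expect_equal(confusable_set(P, 2, 0.05), 1:16)   # 1/16 >= 0.05
  expect_length(confusable_set(P, 2, 0.5), 0)
})

test_that("selection equals exhaustive enumeration on random posterior tables", {
  set.seed(123)
  for (trial in 1:400) {
    n <- sample(1:6, 1)
    tab <- rand_table(n, quantize = trial %% 3 == 0)
    p0 <- sample(c(0.05, 0.1, 0.3, 0.5, 0.9), 1)
    bi <- brute_select(tab, p0)
    i_star <- select_key_atom(tab, p0)
    expect_identical(is.na(i_star), is.na(bi$i))
    if (!is.na(i_star)) {
      expect_equal(i_star, bi$i)
      k_star <- select_replacement(tab, i_star, p0)
      expect_identical(is.na(k_star), is.na(bi$k))
      if (!is.na(k_star)) expect_equal(k_star, bi$k)
    }
  }
})

test_that("degenerate selection cases behave as specified", {
  # all elements confusable at every atom -> no key atom
  tab <- rand_table(3)
  tab$P_recon <- matrix(1 / 16, 3, 16)
  expect_true(is.na(select_key_atom(tab, 1e-6)))
  # single atom: selected whenever its admissible set is nonempty
  tab1 <- rand_table(1)
  tab1$P_recon[1, ] <- c(0.9, rep(0.1 / 15, 15))
  expect_equal(select_key_atom(tab1, 0.5), 1)
  # optimization row one-hot at the original symbol -> no replacement
  tab1$P_opt[1, ] <- c(rep(1e-9, 15), 1 - 15e-9)
  tab1$sym <- 16L
  expect_true(is.na(select_replacement(tab1, 1, 0.5)))
  # the larger of two above-threshold candidates wins
  tab1$P_opt[1, ] <- 0; tab1$P_opt[1, 3] <- 0.55; tab1$P_opt[1, 8] <- 0.40
  tab1$P_opt[1, 16] <- 0.05; tab1$sym <- 16L
  expect_equal(select_replacement(tab1, 1, 0.3), 3)
})

test_that("validity loss matches its closed forms", {
  P <- matrix(0.5, 2, 16)
  expect_equal(validity_loss(P, 1, 3, val_flag = 0), 0)
  expect_equal(validity_loss(P, 1, 3, val_flag = 1), log(2), tolerance = 1e-12)
  # monotone in the confidence of the invalid assignment
  P[1, 3] <- 0.9
  expect_gt(validity_loss(P, 1, 3, 1), log(2))
})

test_that("batched training-time selection agrees with the per-molecule path", {
  m <- fixture_model()
  fx <- fixture_data()
  graphs <- parse_smiles(fx$data$smiles[1:12])
  batch <- cliffopt:::build_batch(graphs)
  set.seed(77)
  p_rec <- matrix(stats::rexp(batch$n_atoms * 16), ncol = 16)
  p_rec <- p_rec / rowSums(p_rec)
  p_opt <- matrix(stats::rexp(batch$n_atoms * 16), ncol = 16)
  p_opt <- p_opt / rowSums(p_opt)
  sel <- cliffopt:::.select_batch(batch, p_rec, p_opt, 0.2)
  for (mm in seq_along(graphs)) {
    rows <- which(batch$mol == mm)
    tab <- list(P_recon = p_rec[rows, , drop = FALSE],
                P_opt = p_opt[rows, , drop = FALSE],
                sym = batch$sym[rows])
    i <- select_key_atom(tab, 0.2)
    expect_identical(sel$i_star[mm], i)
    if (!is.na(i)) {
      expect_identical(sel$k_star[mm], select_replacement(tab, i, 0.2))
    }
  }
})

test_that("posterior tables are row-stochastic and reproducible per seed", {
  m <- fixture_model()
  g <- parse_smiles(fixture_data()$data$smiles[2])
  set.seed(55)
  tab <- posterior_tables(m, g, "forward")
  expect_simplex_rows(tab$P_recon)
  expect_simplex_rows(tab$P_opt)
  set.seed(55)
  tab2 <- posterior_tables(m, g, "forward")
  expect_identical(tab$P_opt, tab2$P_opt)
  # forward and reverse share the reconstruction branch
  set.seed(55)
  tabr <- posterior_tables(m, g, "reverse")
  expect_identical(tab$P_recon, tabr$P_recon)
})

test_that("every emitted molecule is valid and one atom away from its anchor", {
  m <- fixture_model()
  fx <- fixture_data()
  set.seed(66)
  res <- optimize_ligands(m, fx$data[1:25, ], direction = "forward")
  expect_equal(nrow(res), 25)
  emitted <- res[res$status == "selected", ]
  for (r in seq_len(nrow(emitted))) {
    ga <- parse_smiles(emitted$anchor_smiles[r])
    go <- parse_smiles(emitted$optimized_smiles[r])  # sanitizes by parsing
    expect_false(is.na(single_atom_difference(ga, go)))
    k <- which(element_vocabulary()$symbol == emitted$new_symbol[r])
    expect_equal(check_assignment_valid(ga, emitted$atom_index[r], k), 0)
    expect_gte(emitted$confidence[r], m$config$p0)
  }
})

test_that("the random baseline emits valid single-atom edits with full schema", {
  fx <- fixture_data()
  set.seed(88)
  base <- random_substitution_baseline(fx$data[1:10, ])
  expect_named(base, c("anchor_smiles", "optimized_smiles", "atom_index",
                       "old_symbol", "new_symbol", "confidence", "status"))
  ok <- base[base$status == "selected", ]
  expect_gt(nrow(ok), 0)
  for (r in seq_len(nrow(ok))) {
    expect_false(is.na(single_atom_difference(
      parse_smiles(ok$anchor_smiles[r]), parse_smiles(ok$optimized_smiles[r]))))
  }
})

test_that("forward optimization raises predicted activity above reverse", {
  m <- fixture_model()
  fx <- fixture_data()
  anchors <- fx$data[fx$data$site_element == "O", ][1:12, ]
  set.seed(99)
  fwd <- optimize_ligands(m, anchors, "forward")
  set.seed(99)
  rev <- optimize_ligands(m, anchors, "reverse")
  pick <- function(res) {
    smi <- res$optimized_smiles[!is.na(res$optimized_smiles)]
    if (!length(smi)) return(NA_real_)
    mean(predict(m, tibble::tibble(smiles = smi))$.pred)
  }
  pf <- pick(fwd); pr <- pick(rev)
  if (!is.na(pf) && !is.na(pr)) expect_gte(pf, pr)
  expect_true(!is.na(pf) || !is.na(pr))
})
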