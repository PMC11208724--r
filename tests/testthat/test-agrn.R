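test_that("embedding decomposition is the documented softmax", {
  # inner products (0, log 2, log 4) must give exactly (1/7, 2/7, 4/7)
  H <- rbind(c(0, 0), c(log(2), 0), c(log(4), 0))
  g <- decompose(c(1, 0), H)
  expect_equal(g, c(1, 2, 4) / 7, tolerance = 1e-12)
  # equal inner products give the uniform distribution
  expect_equal(decompose(c(0, 0), matrix(rnorm(8), 4, 2)), rep(0.25, 4))
  set.seed(1)
  for (q in 1:10) {
    gam <- decompose(rnorm(3), matrix(rnorm(15), 5, 3))
    expect_equal(sum(gam), 1, tolerance = 1e-9)
    expect_true(all(gam > 0))
  }
})

test_that("molecule-to-atom starts at gamma_i f_in + h_i and stays nonnegative", {
  m <- tiny_model(seed = 13, hidden_dim = 8)
  g <- parse_smiles("CCCO")
  e <- encode(m, g)
  f_in <- e$f + rnorm(8, sd = 0.1)
  gam <- decompose(f_in, e$H)
  out <- molecule_to_atom(m, f_in, e$H, gamma = gam)
  expect_equal(out$gT, gam %o% f_in + e$H, tolerance = 1e-12)
  expect_true(all(out$g0 >= 0))
  expect_equal(dim(out$g0), dim(e$H))
})

test_that("atom-to-atom attention normalizes over every neighborhood", {
  m <- tiny_model(seed = 14, hidden_dim = 8)
  g <- parse_smiles("CC(C)CC(O)C")
  e <- encode(m, g)
  g0 <- molecule_to_atom(m, e$f, e$H)$g0
  st <- atom_to_atom(m, g0, g)
  expect_length(st$attention, m$config$n_layers)
  for (w in st$attention) {
    sums <- tapply(w, st$edges$dst, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
  # an atom with a single neighbor receives weight exactly 1
  chain <- parse_smiles("CCO")
  ec <- encode(m, chain)
  stc <- atom_to_atom(m, molecule_to_atom(m, ec$f, ec$H)$g0, chain)
  deg1 <- which(tabulate(stc$edges$dst) == 1)
  for (w in stc$attention) {
    expect_true(all(abs(w[stc$edges$dst %in% deg1] - 1) < 1e-12))
  }
})

test_that("generation head emits row-stochastic element probabilities", {
  m <- tiny_model(seed = 15, hidden_dim = 8)
  g <- parse_smiles("CCCCO")
  out <- decode(m, g)
  expect_equal(dim(out$atom_probs), c(5, 16))
  expect_simplex_rows(out$atom_probs)
  # deterministic in evaluation mode
  out2 <- decode(m, g)
  expect_identical(out$atom_probs, out2$atom_probs)
})

test_that("zero perturbation reproduces the reconstruction branch exactly", {
  m <- tiny_model(seed = 16, hidden_dim = 10)
  for (smi in c("CCO", "c1ccccc1", "CC(C)CC(O)C", "C")) {
    g <- parse_smiles(smi)
    enc <- encode(m, g)
    a <- decode(m, g, d = NULL, direction = 0, encoded = enc)
    b <- decode(m, g, d = rep(0, 10), direction = 1, encoded = enc)
    expect_identical(a$atom_probs, b$atom_probs)
  }
})

test_that("forward and reverse decoding differ for a nonzero perturbation", {
  m <- fixture_model()
  g <- parse_smiles(fixture_data()$data$smiles[1])
  enc <- encode(m, g)
  set.seed(31)
  d <- adversarial_perturbation(m, enc$f)$d
  fwd <- decode(m, g, d = d, direction = 1, encoded = enc)
  rev <- decode(m, g, d = d, direction = -1, encoded = enc)
  expect_gt(max(abs(fwd$atom_probs - rev$atom_probs)), 1e-8)
})

test_that("the composite decode equals the chained stage functions", {
  m <- tiny_model(seed = 17, hidden_dim = 8)
  g <- parse_smiles("CCC(C)CO")
  enc <- encode(m, g)
  d <- rnorm(8, sd = 0.5)
  via_decode <- decode(m, g, d = d, direction = 1, encoded = enc)
  f_in <- enc$f + d
  gam <- decompose(f_in, enc$H)
  g0 <- molecule_to_atom(m, f_in, enc$H, gamma = gam)$g0
  st <- atom_to_atom(m, g0, g)
  probs <- generate_features(m, st$g_atoms)$atom_probs
  expect_equal(via_decode$atom_probs, probs, tolerance = 1e-12)
  expect_equal(via_decode$gamma, gam, tolerance = 1e-12)
})

test_that("decoding is equivariant under atom relabeling", {
  m <- tiny_model(seed = 18, hidden_dim = 8)
  g <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  n <- n_atoms(g)
  set.seed(2)
  perm <- sample(n)
  inv <- match(seq_len(n), perm)
  atoms2 <- g$atoms[perm, ]
  bonds2 <- g$bonds; bonds2$i <- inv[bonds2$i]; bonds2$j <- inv[bonds2$j]
  g2 <- new_mol_graph(atoms2, bonds2)
  a1 <- decode(m, g)$atom_probs
  a2 <- decode(m, g2)$atom_probs
  expect_equal(a2, a1[perm, ], tolerance = 1e-8)
})

test_that("weighted cross-entropy matches its closed forms", {
  # a single-element molecule has zero loss whatever the prediction
  probs <- matrix(runif(4 * 16), 4); probs <- probs / rowSums(probs)
  expect_equal(weighted_ce(probs, rep(2L, 4)), 0)
  # a perfect one-hot prediction has zero loss
  k <- c(2L, 4L)
  perfect <- matrix(1e-12, 2, 16); perfect[cbind(1:2, k)] <- 1
  expect_equal(weighted_ce(perfect, k), 0, tolerance = 1e-9)
  # two atoms (C, O) under a uniform prediction: each weight 1/2 -> ln 16
  uni <- matrix(1 / 16, 2, 16)
  expect_equal(weighted_ce(uni, k), log(16), tolerance = 1e-9)
})

test_that("reconstruction loss reduces to the atom term by default", {
  m <- tiny_model(seed = 19, hidden_dim = 8)
  g <- parse_smiles("CCOC")
  rec <- decode(m, g)
  expect_equal(reconstruction_loss(rec, g),
               weighted_ce(rec$atom_probs, g) / n_atoms(g))
  # perfect reconstruction costs nothing
  k <- g$atoms$symbol_index
  perfect <- matrix(1e-12, n_atoms(g), 16)
  perfect[cbind(seq_len(n_atoms(g)), k)] <- 1
  expect_equal(reconstruction_loss(list(atom_probs = perfect), g), 0,
               tolerance = 1e-9)
})

test_that("reconstruction rate is chance-like untrained and 1 when trained", {
  fx <- fixture_data()
  m0 <- tiny_model(seed = 20, hidden_dim = 16)
  r0 <- reconstruction_rate(m0, fx$data[1:40, ])
  expect_lt(r0, 0.5)
  m <- fixture_model()
  r1 <- reconstruction_rate(m, fx$data[1:40, ])
  expect_gt(r1, r0)
  # invariant to dataset ordering
  expect_equal(reconstruction_rate(m, fx$data[10:1, ]),
               reconstruction_rate(m, fx$data[1:10, ]))
})
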