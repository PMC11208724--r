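test_that("SMILES parsing yields the expected heavy-atom graphs", {
  g <- parse_smiles("CCO")
  expect_equal(n_atoms(g), 3)
  expect_equal(nrow(g$bonds), 2)
  expect_equal(g$atoms$symbol, c("C", "C", "O"))
  expect_true(all(g$bonds$order == "single"))

  b <- parse_smiles("c1ccccc1")
  expect_equal(n_atoms(b), 6)
  expect_equal(nrow(b$bonds), 6)
  expect_true(all(b$bonds$order == "aromatic"))
  expect_true(all(b$bonds$in_ring))
  expect_true(all(b$atoms$is_aromatic))
})

test_that("unsupported elements and fragments are rejected with clear errors", {
  expect_error(parse_smiles("[U]"), "unsupported element.*U")
  expect_error(parse_smiles("CC.CC"), "multi-fragment")
})

test_that("canonicalization identifies molecules up to atom relabeling", {
  expect_identical(to_canonical_smiles(parse_smiles("OCC")),
                   to_canonical_smiles(parse_smiles("CCO")))
  expect_false(to_canonical_smiles(parse_smiles("CCO")) ==
                 to_canonical_smiles(parse_smiles("CCS")))
  # round trip is the identity on canonical text
  smi <- to_canonical_smiles(parse_smiles("CC(C)c1ccccc1O"))
  expect_identical(to_canonical_smiles(parse_smiles(smi)), smi)
})

test_that("featurize produces the documented schema", {
  g <- parse_smiles("CCO")
  f <- featurize(g)
  expect_equal(dim(f$atoms), c(3, 29))
  # every symbol block is one-hot
  expect_true(all(rowSums(f$atoms[, 1:16]) == 1))
  # the oxygen row: symbol O, degree 1, charge 0, not aromatic, one H
  o <- f$atoms[3, ]
  expect_equal(which(o[1:16] == 1), which(element_vocabulary()$symbol == "O"))
  expect_equal(which(o[17:22] == 1) - 1, 1)  # degree block
  expect_equal(o[23], 0)
  expect_equal(o[24], 0)
  expect_equal(which(o[25:29] == 1) - 1, 1)  # implicit-H block
  bz <- featurize(parse_smiles("c1ccccc1"))
  expect_true(all(bz$bonds[, 4] == 1))  # aromatic order one-hot
  expect_true(all(bz$bonds[, 6] == 1))  # in-ring flag
})

test_that("featurize is permutation-equivariant", {
  g <- parse_smiles("CC(=O)Nc1ccc(O)cc1")
  n <- n_atoms(g)
  set.seed(1)
  perm <- sample(n)
  inv <- match(seq_len(n), perm)
  atoms2 <- g$atoms[perm, ]
  bonds2 <- g$bonds
  bonds2$i <- inv[g$bonds$i]
  bonds2$j <- inv[g$bonds$j]
  g2 <- new_mol_graph(atoms2, bonds2)
  f1 <- featurize(g)
  f2 <- featurize(g2)
  expect_equal(f2$atoms, f1$atoms[perm, ])
})

test_that("valence mask follows the documented arithmetic", {
  propane <- parse_smiles("CCC")
  k_of <- function(s) which(element_vocabulary()$symbol == s)
  expect_equal(check_assignment_valid(propane, 2, k_of("F")), 1)
  expect_equal(check_assignment_valid(parse_smiles("CC"), 1, k_of("N")), 0)
  # identity assignment is always valid, even at ring-fusion carbons
  naph <- parse_smiles("c1ccc2ccccc2c1")
  for (i in seq_len(n_atoms(naph))) {
    expect_equal(check_assignment_valid(naph, i, naph$atoms$symbol_index[i]), 0)
  }
  # "other" is never a legal target
  expect_equal(check_assignment_valid(propane, 1, 16), 1)
})

test_that("substitution rewrites exactly one atom and keeps all bonds", {
  g <- parse_smiles("CCO")
  k_s <- which(element_vocabulary()$symbol == "S")
  s <- substitute_atom(g, 3, k_s)
  expect_identical(to_canonical_smiles(s), to_canonical_smiles(parse_smiles("CCS")))
  expect_equal(s$bonds, g$bonds)
  diffs <- sum(s$atoms$symbol != g$atoms$symbol)
  expect_equal(diffs, 1)
  # no-op substitution returns an identical graph
  k_o <- which(element_vocabulary()$symbol == "O")
  expect_identical(substitute_atom(g, 3, k_o)$atoms, g$atoms)
  expect_error(substitute_atom(parse_smiles("CCC"), 2,
                               which(element_vocabulary()$symbol == "F")),
               "valence violation")
})

test_that("valid-claimed substitutions sanitize under an independent toolkit", {
  # cross-check the arithmetic valence mask against RDKit sanitization
  set.seed(42)
  fx <- generate_fixture(fixture_config(n_scaffolds = 8, n_background = 8,
                                        seed = 42))
  extra <- c("c1ccccc1", "Cc1ccccc1", "c1ccncc1", "CC(=O)O", "CC(C)=CC",
             "C#CC", "CCOC", "CN(C)C", "C1CCOC1")
  graphs <- parse_smiles(c(fx$data$smiles, extra))
  smis <- character(0)
  n_checked <- 0
  while (n_checked < 1000) {
    g <- graphs[[sample(length(graphs), 1)]]
    i <- sample(n_atoms(g), 1)
    k <- sample(16, 1)
    n_checked <- n_checked + 1
    if (k == g$atoms$symbol_index[i]) next
    if (check_assignment_valid(g, i, k) == 0) {
      smis <- c(smis, to_canonical_smiles(substitute_atom(g, i, k)))
    }
  }
  expect_gt(length(smis), 100)
  tf <- tempfile(fileext = ".txt")
  writeLines(smis, tf)
  out <- system2("python", c("-c", shQuote(paste0(
    "from rdkit import Chem\n",
    "from rdkit import RDLogger\n",
    "RDLogger.DisableLog('rdApp.*')\n",
    "bad = 0\n",
    "for line in open('", tf, "'):\n",
    "    if Chem.MolFromSmiles(line.strip()) is None: bad += 1\n",
    "print(bad)"))), stdout = TRUE)
  expect_identical(trimws(out[length(out)]), "0")
})

test_that("molecule CSV round-trips through the readers and writers", {
  tf <- tempfile(fileext = ".csv")
  df <- tibble::tibble(smiles = c("CCO", "CCS"), pIC50 = c(5.1, 7.3))
  utils::write.csv(df, tf, row.names = FALSE)
  rd <- read_molecule_csv(tf)
  expect_equal(rd$smiles, df$smiles)
  expect_equal(rd$activity, df$pIC50)
  expect_error(read_molecule_csv(tempfile()), "not found")
})
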