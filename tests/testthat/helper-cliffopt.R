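# shared fixtures for the suite; everything is generated in code

.test_env <- new.env(parent = emptyenv())

# small untrained model (random parameters under a fixed seed)
tiny_model <- function(seed = 1, hidden_dim = 8, ...) {
  cfg <- cliffopt_config(hidden_dim = hidden_dim, seed = seed, ...)
  set.seed(seed)
  structure(list(params = cliffopt:::init_params(cfg), config = cfg,
                 vocab_hash = vocabulary_hash()),
            class = "cliffopt_model")
}

# a small trained model on a planted-rule fixture, cached across tests
fixture_model <- function() {
  if (!is.null(.test_env$model)) return(.test_env$model)
  fx <- generate_fixture(fixture_config(n_scaffolds = 30, n_background = 40,
                                        seed = 7))
  cfg <- cliffopt_config(hidden_dim = 16, epochs = 50, seed = 7)
  m <- cliffopt_fit(fx$data[, c("smiles", "activity")], cfg)
  .test_env$model <- m
  .test_env$fixture <- fx
  m
}

fixture_data <- function() {
  fixture_model()
  .test_env$fixture
}

# a hand-built model whose predictor is exactly N(f1, f2) = w . f2 + const
# (relu layer forced into its linear region by a large bias)
linear_predictor_model <- function(w, hidden_dim = length(w)) {
  m <- tiny_model(seed = 3, hidden_dim = hidden_dim)
  d <- hidden_dim
  W1 <- matrix(0, 2 * d, d)
  W1[(d + 1):(2 * d), ] <- diag(d)   # hidden = relu(f2 + 100) = f2 + 100
  m$params$pred.h.W <- W1
  m$params$pred.h.b <- matrix(100, 1, d)
  m$params$pred.out.W <- matrix(w, d, 1)
  m$params$pred.out.b <- matrix(0)
  m
}

expect_simplex_rows <- function(p, tol = 1e-6) {
  expect_true(all(abs(rowSums(p) - 1) < tol))
  expect_true(all(p > 0))
}
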