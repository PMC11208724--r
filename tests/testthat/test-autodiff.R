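# Finite-difference verification of the reverse-mode tape. Every operator
# used by the models appears in at least one of the composite graphs below.

num_grad <- function(param, fval, eps = 1e-6) {
  g <- param * 0
  for (q in seq_along(param)) {
    p1 <- param; p1[q] <- p1[q] + eps
    p2 <- param; p2[q] <- p2[q] - eps
    g[q] <- (fval(p1) - fval(p2)) / (2 * eps)
  }
  g
}

test_that("dense + activation + softmax chain matches finite differences", {
  ad <- asNamespace("cliffopt")
  run <- function(W, b, X) {
    tp <- ad$ad_tape()
    Wi <- ad$ad_leaf(tp, W, "W"); bi <- ad$ad_leaf(tp, b, "b")
    Xi <- ad$ad_const(tp, X)
    h <- ad$ad_elu(tp, ad$ad_add_bias(tp, ad$ad_matmul(tp, Xi, Wi), bi))
    h <- ad$ad_tanh(tp, h)
    h <- ad$ad_sigmoid(tp, h)
    p <- ad$ad_softmax_rows(tp, h)
    loss <- ad$ad_sum(tp, ad$ad_mul(tp, p, p))
    list(v = as.numeric(ad$ad_val(tp, loss)), tp = tp, id = loss)
  }
  set.seed(2)
  W <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(3), 1); X <- matrix(rnorm(20), 5, 4)
  r <- run(W, b, X)
  gr <- ad$ad_backward(r$tp, r$id)
  expect_lt(max(abs(gr$W - num_grad(W, function(p) run(p, b, X)$v))), 1e-6)
  expect_lt(max(abs(gr$b - num_grad(b, function(p) run(W, p, X)$v))), 1e-6)
})

test_that("segment/gather graph ops match finite differences", {
  ad <- asNamespace("cliffopt")
  idx <- c(1, 2, 2, 3, 3, 1, 2)
  grp <- c(1, 1, 2, 2, 3, 3, 3)
  run <- function(M) {
    tp <- ad$ad_tape()
    Mi <- ad$ad_leaf(tp, M, "M")
    e <- ad$ad_gather_rows(tp, Mi, idx)
    s <- ad$ad_rowsums(tp, ad$ad_mul(tp, e, e))
    w <- ad$ad_segment_softmax(tp, s, grp)
    agg <- ad$ad_segment_sum(tp, ad$ad_colscale(tp, e, w), grp, 3)
    sl <- ad$ad_slice_cols(tp, agg, 1:2)
    pick <- ad$ad_gather_entries(tp, agg, c(1, 3), c(2, 1))
    l1 <- ad$ad_sum(tp, ad$ad_leaky_relu(tp, sl))
    l2 <- ad$ad_sum(tp, ad$ad_log(tp, ad$ad_relu(tp, pick), clamp = 1e-9))
    loss <- ad$ad_add(tp, l1, l2)
    list(v = as.numeric(ad$ad_val(tp, loss)), tp = tp, id = loss)
  }
  set.seed(3)
  M <- matrix(rnorm(9, sd = 0.5) + 1, 3, 3)
  r <- run(M)
  gr <- ad$ad_backward(r$tp, r$id)
  expect_lt(max(abs(gr$M - num_grad(M, function(p) run(p)$v))), 1e-5)
})

test_that("GRU cell gradient matches finite differences", {
  ad <- asNamespace("cliffopt")
  set.seed(4)
  d <- 4
  params <- cliffopt:::.gru_init(d, d)
  names(params) <- paste0("g.", names(params))
  x <- matrix(rnorm(2 * d), 2, d)
  h0 <- matrix(rnorm(2 * d), 2, d)
  run <- function(params) {
    tp <- ad$ad_tape()
    P <- cliffopt:::.param_binder(tp, params)
    out <- cliffopt:::.ad_gru_step(tp, P, "g", ad$ad_const(tp, x),
                                   ad$ad_const(tp, h0))
    loss <- ad$ad_sum(tp, ad$ad_mul(tp, out, out))
    list(v = as.numeric(ad$ad_val(tp, loss)), tp = tp, id = loss)
  }
  r <- run(params)
  gr <- ad$ad_backward(r$tp, r$id)
  for (nm in c("g.Wxz", "g.Whh", "g.bz", "g.br")) {
    fv <- function(p) { pp <- params; pp[[nm]] <- p; run(pp)$v }
    expect_lt(max(abs(gr[[nm]] - num_grad(params[[nm]], fv))), 1e-6)
  }
})

test_that("the full training objective gradient matches finite differences", {
  # end-to-end check through encoder, predictor, both decoder branches
  graphs <- parse_smiles(c("CCO", "CCS", "CC(C)O"))
  cfg <- cliffopt_config(hidden_dim = 5, seed = 9)
  set.seed(9)
  params <- cliffopt:::init_params(cfg)
  batch <- cliffopt:::build_batch(graphs)
  y <- c(5, 7, 5.5)
  d_fixed <- matrix(0.3, 3, 5)  # frozen perturbation: objective is then smooth
  loss_of <- function(params) {
    ad <- asNamespace("cliffopt")
    tp <- ad$ad_tape()
    P <- cliffopt:::.param_binder(tp, params)
    e <- cliffopt:::enc_forward(tp, P, batch, cfg, NULL)
    pred0 <- cliffopt:::pred_forward(tp, P, e$f, e$f)
    l_bio <- cliffopt:::bio_loss_node(tp, pred0, y, "regression")
    predd <- cliffopt:::pred_forward(tp, P, e$f,
                                     ad$ad_add(tp, e$f, ad$ad_const(tp, d_fixed)))
    err <- ad$ad_sub(tp, pred0, predd)
    l_afse <- ad$ad_affine(tp, ad$ad_sum(tp, ad$ad_mul(tp, err, err)), 1 / 3)
    rec <- cliffopt:::dec_forward(tp, P, batch, e$H, e$f, cfg, NULL)
    l_rec <- cliffopt:::recon_loss_node(tp, batch, rec$atom_probs)
    total <- ad$ad_add(tp, l_bio, ad$ad_add(tp, ad$ad_affine(tp, l_afse, 0.6),
                                            ad$ad_affine(tp, l_rec, 0.3)))
    list(v = as.numeric(ad$ad_val(tp, total)), tp = tp, id = total)
  }
  r <- loss_of(params)
  gr <- asNamespace("cliffopt")$ad_backward(r$tp, r$id)
  set.seed(10)
  picks <- c("enc.in.W", "enc.l2.att.W", "enc.l1.gru.Whz", "pred.h.W",
             "dec.rel.W", "dec.att.W", "dec.gru2.Wxh", "dec.atom.W")
  for (nm in picks) {
    fv <- function(p) { pp <- params; pp[[nm]] <- p; loss_of(pp)$v }
    num <- num_grad(params[[nm]], fv, eps = 1e-5)
    denom <- max(abs(num), 1e-8)
    expect_lt(max(abs(gr[[nm]] - num)) / denom, 1e-3)
  }
})
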