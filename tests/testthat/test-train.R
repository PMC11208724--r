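test_that("learning-rate schedule ramps up and decays to zero", {
  expect_equal(lr_schedule(0, 100, 0.01, 0.1), 0)
  expect_equal(lr_schedule(10, 100, 0.01, 0.1), 0.01)   # end of warm-up
  expect_equal(lr_schedule(100, 100, 0.01, 0.1), 0)
  expect_equal(lr_schedule(55, 100, 0.01, 0.1), 0.01 * 45 / 90)
  mid <- vapply(0:100, lr_schedule, numeric(1), total_steps = 100,
                base_rate = 0.01, warmup_fraction = 0.1)
  expect_equal(which.max(mid) - 1, 10)
  expect_true(all(mid >= 0))
})

test_that("the total objective reduces to the task loss when lambdas vanish", {
  fx <- fixture_data()
  m <- fixture_model()
  m$config$lambda1 <- 0
  m$config$lambda2 <- 0
  set.seed(12)
  comps <- total_objective(m, fx$data[1:16, c("smiles", "activity")])
  expect_equal(comps$total, comps$bio, tolerance = 1e-12)
  expect_gte(comps$afse, 0)
  expect_gte(comps$recon, 0)
  expect_gte(comps$val, 0)
  # with the published coefficients the weighted parts add on top
  m$config$lambda1 <- 0.6
  m$config$lambda2 <- 0.3
  set.seed(12)
  comps2 <- total_objective(m, fx$data[1:16, c("smiles", "activity")])
  expect_gte(comps2$total, comps2$bio)
  expect_equal(comps2$total,
               comps2$bio + 0.6 * comps2$afse + 0.3 * (comps2$recon + comps2$val),
               tolerance = 1e-12)
})

test_that("a short smoke run trains, records history, and is deterministic", {
  fx <- generate_fixture(fixture_config(n_scaffolds = 8, n_background = 9,
                                        seed = 21))
  cfg <- cliffopt_config(hidden_dim = 8, epochs = 2, seed = 5)
  m1 <- cliffopt_fit(fx$data[, c("smiles", "activity")], cfg)
  expect_s3_class(m1, "cliffopt_model")
  expect_equal(nrow(m1$history), 2)
  expect_true(all(c("l_bio", "l_afse", "l_recon", "l_val",
                    "reconstruction_rate", "validity_rate", "val_metric")
                  %in% names(m1$history)))
  m2 <- cliffopt_fit(fx$data[, c("smiles", "activity")], cfg)
  expect_equal(m1$history$total, m2$history$total, tolerance = 1e-10)
  expect_equal(m1$params, m2$params, tolerance = 1e-10)
})

test_that("the task loss decreases over the first epochs across seeds", {
  fx <- fixture_data()
  wins <- 0
  for (s in 1:5) {
    cfg <- cliffopt_config(hidden_dim = 8, epochs = 5, seed = 30 + s)
    m <- cliffopt_fit(fx$data[, c("smiles", "activity")], cfg)
    h <- m$history$l_bio
    if (h[5] < h[1]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("best-model rule picks the highest rate sum, earliest on ties", {
  h <- tibble::tibble(
    reconstruction_rate = c(0.5, 0.9, 0.95),
    validity_rate = c(0.5, 0.8, 0.6)
  )
  expect_equal(select_best_model(h), 2)
  h2 <- tibble::tibble(reconstruction_rate = c(0.7, 0.7),
                       validity_rate = c(0.2, 0.2))
  expect_equal(select_best_model(h2), 1)
  h3 <- tibble::tibble(reconstruction_rate = 0.4, validity_rate = NA)
  expect_equal(select_best_model(h3), 1)
  cps <- list("a", "b", "c")
  expect_identical(select_best_model(h, cps), "b")
  # monotone rates pick the last epoch
  h4 <- tibble::tibble(reconstruction_rate = c(0.1, 0.5, 0.9),
                       validity_rate = c(0.1, 0.5, 0.9))
  expect_equal(select_best_model(h4), 3)
})

test_that("validity rate lies in the unit interval or is not applicable", {
  m <- fixture_model()
  fx <- fixture_data()
  vr <- validity_rate(m, fx$data[1:20, ])
  expect_true(is.na(vr) || (vr >= 0 && vr <= 1))
})

test_that("classification task trains and scores sensibly", {
  fx <- generate_classification_fixture(
    fixture_config(n_scaffolds = 10, n_background = 12, seed = 23))
  cfg <- cliffopt_config(hidden_dim = 8, epochs = 4, seed = 4,
                         task = "classification")
  m <- cliffopt_fit(fx$data[, c("smiles", "activity")], cfg)
  pr <- predict(m, fx$data)
  expect_true(all(pr$.pred >= 0 & pr$.pred <= 1))
  cm <- classification_metrics(fx$data$activity, pr$.pred)
  expect_true(is.finite(cm$auroc))
})

test_that("checkpoints round-trip through JSON exactly", {
  m <- fixture_model()
  tf <- tempfile(fileext = ".json")
  write_cliffopt(m, tf)
  m2 <- read_cliffopt(tf)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_equal(m2$config$hidden_dim, m$config$hidden_dim)
  g <- parse_smiles("CCCO")
  expect_equal(encode(m2, g)$f, encode(m, g)$f, tolerance = 1e-12)
})

test_that("tidy, glance and autoplot expose the training history", {
  m <- fixture_model()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(m$history))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$best_epoch, m$best_epoch)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})
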