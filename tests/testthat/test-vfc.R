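test_that("closed-form Gaussian KL matches hand values and is non-negative", {
  expect_equal(gaussian_kl(1, 2), 0.5 * (4 + 1 - 1 - log(4)))
  expect_equal(gaussian_kl(0, 1), 0)
  expect_equal(gaussian_kl(c(0, 0), c(1, 1)), 0)
  set.seed(4)
  mu <- matrix(rnorm(50), 10, 5)
  sigma <- matrix(rexp(50) + 0.05, 10, 5)
  kl <- gaussian_kl(mu, sigma)
  expect_true(all(kl >= 0))
  # zero iff the posterior equals the prior
  expect_true(all(kl[rowSums(mu != 0 | sigma != 1) > 0] > 0))
})

test_that("closed-form KL agrees with a Monte-Carlo estimate within 3 SE", {
  set.seed(9)
  for (case in 1:5) {
    mu <- rnorm(1); sigma <- rexp(1) + 0.2
    z <- rnorm(1e5, mu, sigma)
    terms <- dnorm(z, mu, sigma, log = TRUE) - dnorm(z, log = TRUE)
    mc <- mean(terms); se <- sd(terms) / sqrt(length(terms))
    expect_lt(abs(gaussian_kl(mu, sigma) - mc), 3 * se)
  }
})

test_that("the loss reduces to the classification NLL at lambda = 0", {
  ds <- signal_dataset(n = 60, d = 10, seed = 1)
  cfg0 <- vfc_config(input_dim = 10, hidden_dims = c(16, 8), latent_dim = 4,
                     lambda = 0, epochs = 5, seed = 2)
  m <- vfc_fit(ds, cfg0)
  set.seed(1)
  l <- vfc_loss(ds$features, ds$labels, m)
  expect_equal(l$loss, l$nll)
  expect_gt(l$kl, 0)

  # linear decomposition: with identical parameters, loss(lambda) = nll + lambda * kl
  m2 <- m; m2$config$lambda <- 0.7
  set.seed(1)
  l2 <- vfc_loss(ds$features, ds$labels, m2)
  expect_equal(l2$nll, l$nll)
  expect_equal(l2$kl, l$kl)
  expect_equal(l2$loss, l2$nll + 0.7 * l2$kl)
})

test_that("a posterior pinned to the prior has zero KL component", {
  cfg <- vfc_config(input_dim = 6, hidden_dims = c(8), latent_dim = 3,
                    epochs = 1, seed = 3)
  set.seed(3)
  m <- structure(list(params = antioxpred:::vfc_init_params(cfg),
                      standardizer = list(center = rep(0, 6), scale = rep(1, 6)),
                      config = cfg),
                 class = "vfc_model")
  # zero the mean head; fix the scale head at softplus^{-1}(1) so sigma = 1
  m$params$mean_head$W[] <- 0; m$params$mean_head$b[] <- 0
  m$params$scale_head$W[] <- 0
  m$params$scale_head$b[] <- log(exp(1) - 1)
  l <- vfc_loss(matrix(rnorm(30), 5, 6), rep(0:1, length.out = 5), m)
  expect_equal(l$kl, 0, tolerance = 1e-12)
})

test_that("training is seed-deterministic, improves on chance, and lambda collapses KL", {
  ds <- signal_dataset(n = 80, d = 12, k = 3, shift = 3, seed = 6)
  cfg <- vfc_config(input_dim = 12, hidden_dims = c(24, 12), latent_dim = 4,
                    epochs = 40, seed = 11)
  m1 <- vfc_fit(ds, cfg)
  m2 <- vfc_fit(ds, cfg)
  expect_identical(m1$params, m2$params)

  # final training loss not above the initial epoch's
  expect_lte(tail(m1$history$loss, 1), m1$history$loss[1])
  # strongly separable data: NLL beats the chance-level ln 2 of a constant predictor
  expect_lt(tail(m1$history$nll, 1), log(2))

  # a dominant bottleneck weight collapses the posterior onto the prior
  cfg_big <- cfg; cfg_big$lambda <- 100; cfg_big$epochs <- 400L
  m3 <- vfc_fit(ds, cfg_big)
  cfg_small <- cfg; cfg_small$epochs <- 400L
  m4 <- vfc_fit(ds, cfg_small)
  expect_lt(tail(m3$history$kl, 1), 0.05)
  expect_lt(tail(m3$history$kl, 1), 0.01 * tail(m4$history$kl, 1))

  expect_error(vfc_fit(labeled_dataset(ds$ids, ds$features, rep(0L, 80)), cfg),
               "both classes")
  expect_error(vfc_fit(ds, vfc_config(input_dim = 13)), "input_dim")
})

test_that("the latent transform is deterministic, row-wise, and 15-wide by default", {
  ds <- signal_dataset(n = 50, d = 473, k = 5, seed = 7)
  cfg <- vfc_config(epochs = 3, seed = 5)
  m <- vfc_fit(ds, cfg)
  z <- vfc_transform(m, ds$features)
  expect_equal(dim(z), c(50L, 15L))
  expect_identical(z, vfc_transform(m, ds$features))
  # duplicated input rows give duplicated output rows
  zdup <- vfc_transform(m, ds$features[c(1, 1, 2), ])
  expect_identical(zdup[1, ], zdup[2, ])
  expect_equal(zdup[3, ], z[2, ], tolerance = 1e-12)
  expect_error(vfc_transform(m, ds$features[, 1:100]), "input_dim")
})

test_that("multi-run selection returns the highest-MCC run, ties to the lowest index", {
  ds <- signal_dataset(n = 80, d = 10, k = 3, shift = 2.5, seed = 8)
  cfg <- vfc_config(input_dim = 10, hidden_dims = c(16), latent_dim = 3,
                    epochs = 20, n_runs = 3, seed = 13)
  sel <- vfc_select(ds, cfg)
  expect_equal(nrow(sel$report), 3L)
  expect_equal(which(sel$report$selected), which.max(sel$report$val_mcc))

  cfg1 <- cfg; cfg1$n_runs <- 1L
  sel1 <- vfc_select(ds, cfg1)
  expect_equal(nrow(sel1$report), 1L)
  expect_true(sel1$report$selected)

  # a constant downstream predictor makes every run tie; run 1 must win
  constant_trainer <- function(features, labels) {
    structure(list(), class = "constant_clf")
  }
  assign("predict.constant_clf",
         function(object, newdata, type = "label", ...) rep(0L, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.constant_clf", envir = globalenv()), add = TRUE)
  suppressWarnings(sel_tie <- vfc_select(ds, cfg, constant_trainer))
  expect_equal(which(sel_tie$report$selected), 1L)
})

test_that("JSON serialization round-trips the model", {
  ds <- signal_dataset(n = 40, d = 8, seed = 9)
  m <- vfc_fit(ds, vfc_config(input_dim = 8, hidden_dims = c(12, 6),
                              latent_dim = 3, epochs = 5, seed = 21))
  path <- withr::local_tempfile(fileext = ".json")
  vfc_save(m, path)
  back <- vfc_load(path)
  expect_equal(vfc_transform(back, ds$features), vfc_transform(m, ds$features),
               tolerance = 1e-12)
  expect_equal(back$config$latent_dim, 3L)
})

test_that("the 15-D latent retains the class signal of the 473-D features", {
  # labels depend on a low-dimensional signal (five PSSM score columns plus
  # the helix propensity) embedded in the full 473-dimensional vector; the
  # compressed representation must support classification on par with the
  # uncompressed one
  td <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_pos = 100, n_neg = 100,
                                     length_range = c(50, 120),
                                     effect_size = 3, seed = 21), td)
  ds <- extract_dataset(sim$pssm_dir, sim$ss2_dir, sim$labels_file)
  set.seed(99)
  test_idx <- sort(unlist(lapply(split(seq_len(200), ds$labels), sample, 20)))
  train_idx <- setdiff(seq_len(200), test_idx)
  train <- labeled_dataset(ds$ids[train_idx], ds$features[train_idx, ],
                           ds$labels[train_idx])

  full <- gbt_train(train$features, train$labels, gbt_params(seed = 1))
  mcc_of <- function(pred) {
    compute_metrics(confusion_counts(ds$labels[test_idx], pred))$mcc
  }
  mcc_full <- mcc_of(predict(full, ds$features[test_idx, ], type = "label"))

  sel <- vfc_select(train, vfc_config(epochs = 100, n_runs = 3, seed = 17))
  z_train <- vfc_transform(sel$model, train$features)
  z_test <- vfc_transform(sel$model, ds$features[test_idx, ])
  lat <- gbt_train(z_train, train$labels, gbt_params(seed = 1))
  mcc_lat <- mcc_of(predict(lat, z_test, type = "label"))

  expect_gte(mcc_lat, mcc_full - 0.05)
})
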