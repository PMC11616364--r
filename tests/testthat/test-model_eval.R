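counts_of <- function(tp, fp, tn, fn) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), class = "confusion_counts")
}

test_that("metrics match the printed formulas on hand-computed cases", {
  m <- compute_metrics(counts_of(3, 1, 4, 2))
  expect_equal(m$acc, 0.7)
  expect_equal(m$sn, 0.6)
  expect_equal(m$sp, 0.8)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$mcc, 10 / sqrt(600))

  perfect <- compute_metrics(counts_of(5, 0, 5, 0))
  expect_equal(unlist(perfect[c("acc", "sn", "sp", "mcc", "f1")]),
               c(acc = 1, sn = 1, sp = 1, mcc = 1, f1 = 1))

  expect_warning(deg <- compute_metrics(counts_of(0, 2, 8, 0)), "degenerate")
  expect_equal(deg$sn, 0)
  expect_true(deg$degenerate)
  expect_error(compute_metrics(counts_of(0, 0, 0, 0)), "zero")
})

test_that("MCC symmetry and sign-flip properties hold", {
  set.seed(10)
  for (i in 1:20) {
    cts <- as.list(rmultinom(1, 60, c(0.3, 0.2, 0.3, 0.2))[, 1])
    names(cts) <- c("tp", "fp", "tn", "fn")
    m <- suppressWarnings(compute_metrics(counts_of(cts$tp, cts$fp, cts$tn, cts$fn)))
    # class swap (tp<->tn, fp<->fn) leaves MCC unchanged
    sw <- suppressWarnings(compute_metrics(counts_of(cts$tn, cts$fn, cts$tp, cts$fp)))
    expect_equal(sw$mcc, m$mcc)
    # label inversion (truth flipped): tp<->fp, tn<->fn negates MCC
    inv <- suppressWarnings(compute_metrics(counts_of(cts$fp, cts$tp, cts$fn, cts$tn)))
    expect_equal(inv$mcc, -m$mcc)
    # ACC = (SN*P + SP*N) / (P + N)
    P <- cts$tp + cts$fn; N <- cts$tn + cts$fp
    if (P > 0 && N > 0) expect_equal(m$acc, (m$sn * P + m$sp * N) / (P + N))
  }
})

test_that("confusion_counts tallies against truth with label 1 positive", {
  truth <- c(1, 1, 1, 0, 0, 0, 1, 0)
  pred  <- c(1, 0, 1, 0, 1, 0, 1, 0)
  cc <- confusion_counts(truth, pred)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 3L, fp = 1L, tn = 3L, fn = 1L))
})

test_that("the boosted-tree classifier separates trivial data and is seed-stable", {
  x <- rbind(matrix(rnorm(60, -3), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c(0L, 1L), each = 30)
  clf <- gbt_train(x, y, gbt_params(n_trees = 50, seed = 1))
  expect_equal(predict(clf, x, type = "label"), y)
  expect_true(all(predict(clf, x, type = "prob") >= 0 &
                  predict(clf, x, type = "prob") <= 1))

  clf2 <- gbt_train(x, y, gbt_params(n_trees = 50, seed = 1))
  expect_identical(predict(clf, x, type = "prob"), predict(clf2, x, type = "prob"))

  expect_error(gbt_train(x, rep(0L, 60), gbt_params()), "both classes")
  expect_error(predict(clf, x[, 1, drop = FALSE]), "trained on")
})

test_that("held-out accuracy on pure noise stays within the binomial null band", {
  set.seed(20)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c(0L, 1L), each = n / 2)      # labels independent of features
  folds <- antioxpred:::stratified_folds(y, 5, seed = 20)
  correct <- 0L
  for (f in 1:5) {
    clf <- gbt_train(x[folds != f, ], y[folds != f],
                     gbt_params(n_trees = 60, seed = f))
    correct <- correct + sum(predict(clf, x[folds == f, ], type = "label") ==
                             y[folds == f])
  }
  # exact binomial(200, 0.5) null: central 99.9% interval for #correct
  band <- qbinom(c(5e-4, 1 - 5e-4), n, 0.5)
  expect_gte(correct, band[1])
  expect_lte(correct, band[2])
})

test_that("stratified folds are near-equal and class-balanced", {
  set.seed(2)
  for (trial in list(c(100, 5), c(103, 5), c(57, 4))) {
    n <- trial[1]; k <- trial[2]
    y <- as.integer(runif(n) < 0.3)
    folds <- antioxpred:::stratified_folds(y, k, seed = trial[1])
    sizes <- tabulate(folds, k)
    expect_lte(max(sizes) - min(sizes), 1L)
    # each fold's positive count within 1 of the proportional share
    for (f in seq_len(k)) {
      expect_lte(abs(sum(y[folds == f]) - sum(y) * sizes[f] / n), 1)
    }
  }
  expect_error(antioxpred:::stratified_folds(rep(0:1, 2), 5, seed = 1),
               "exceeds")
})

test_that("cross-validation reports fold means and honors both SMOTE orderings", {
  ds <- signal_dataset(n = 70, d = 473, k = 8, shift = 3, seed = 30)
  ds <- labeled_dataset(ds$ids, ds$features,
                        c(rep(1L, 25), rep(0L, 45)))   # imbalanced
  cfg <- pipeline_config(seed = 2,
                         vfc = vfc_config(hidden_dims = c(32, 16),
                                          epochs = 25, n_runs = 1, seed = 2),
                         gbt = gbt_params(n_trees = 60, seed = 2))
  rep_safe <- kfold_cv(ds, k = 3, cfg, mode = "fold-safe")
  expect_equal(nrow(rep_safe$per_fold), 3L)
  expect_equal(unname(rep_safe$averages),
               unname(colMeans(rep_safe$per_fold[, c("acc", "sn", "sp", "mcc", "f1")])))

  rep_paper <- kfold_cv(ds, k = 3, cfg, mode = "paper")
  expect_equal(rep_paper$mode, "paper")
  expect_equal(nrow(rep_paper$per_fold), 3L)
  expect_true(all(rep_paper$per_fold$acc >= 0 & rep_paper$per_fold$acc <= 1))

  path <- withr::local_tempfile(fileext = ".csv")
  write_cv_table(rep_safe, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("Times", "ACC", "SN", "SP", "MCC", "F1"))
  expect_equal(tab$Times, c("1", "2", "3", "Average"))
  expect_equal(tab$ACC[4], round(100 * rep_safe$averages[["acc"]], 2))
})
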