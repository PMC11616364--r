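#' Gradient-boosted-tree hyperparameters
#'
#' The classifier minimizes logistic loss plus the usual tree regularizer
#' `gamma * T + 0.5 * reg_lambda * ||w||^2` (leaf count and leaf weights).
#'
#' @param n_trees Number of boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param max_depth Maximum tree depth.
#' @param gamma Minimum loss reduction per split (leaf-count penalty).
#' @param reg_lambda L2 penalty on leaf weights.
#' @param seed Integer seed for reproducible training.
#' @return An object of class `gbt_params`.
#' @export
gbt_params <- function(n_trees = 300L, learning_rate = 0.1, max_depth = 4L,
                       gamma = 0, reg_lambda = 1, seed = 1L) {
  stopifnot(n_trees >= 1L, gamma >= 0, reg_lambda >= 0)
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), gamma = gamma,
                 reg_lambda = reg_lambda, seed = as.integer(seed)),
            class = "gbt_params")
}

#' Train the gradient-boosted-tree classifier
#'
#' Thin wrapper around xgboost (binary logistic objective, single thread)
#' configured to the regularized objective above. Predictions are the
#' accumulated leaf weights passed through the logistic link; labels are
#' thresholded at 0.5.
#'
#' @param features Numeric n x d matrix.
#' @param labels 0/1 vector of length n.
#' @param params A [gbt_params()].
#' @return An object of class `gbt_classifier`.
#' @export
gbt_train <- function(features, labels, params = gbt_params()) {
  stopifnot(inherits(params, "gbt_params"))
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to train the classifier", call. = FALSE)
  }
  dtrain <- xgboost::xgb.DMatrix(features, label = labels)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth,
                  eta = params$learning_rate,
                  gamma = params$gamma,
                  lambda = params$reg_lambda,
                  nthread = 1L,
                  seed = params$seed),
    data = dtrain, nrounds = params$n_trees, verbose = 0)
  structure(list(booster = booster, params = params, n_features = ncol(features)),
            class = "gbt_classifier")
}

#' Predict with a trained gradient-boosted-tree classifier
#'
#' @param object A [gbt_train()] classifier.
#' @param newdata Numeric matrix with the training dimensionality.
#' @param type `"prob"` for class-1 probabilities, `"label"` for 0/1 labels
#'   (threshold 0.5).
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.gbt_classifier <- function(object, newdata, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; the classifier was trained on ",
         object$n_features, call. = FALSE)
  }
  p <- predict(object$booster, xgboost::xgb.DMatrix(newdata))
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Confusion counts from truth and prediction
#'
#' Positive class is label 1 (antioxidant).
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fp = sum(truth == 0L & predicted == 1L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fn = sum(truth == 1L & predicted == 0L)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' Matthews correlation coefficient
#' `(TN*TP - FN*FP) / sqrt((TN+FP)(FN+TP)(TN+FN)(TP+FP))` and
#' `F1 = 2TP/(2TP+FP+FN)`. A 0/0 denominator yields 0 and sets the
#' `degenerate` flag (with a warning), keeping fold averaging well-defined.
#'
#' @param counts A [confusion_counts()] object or list with tp/fp/tn/fn.
#' @return A list of class `metrics_report` with `acc`, `sn`, `sp`, `mcc`,
#'   `f1`, `counts` and `degenerate`.
#' @export
#' @examples
#' compute_metrics(confusion_counts(c(1,1,1,1,1,0,0,0,0,0),
#'                                  c(1,1,1,0,0,0,0,0,0,1)))
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  acc <- (tn + tp) / total
  sn <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  mcc_den <- sqrt((tn + fp) * (fn + tp) * (tn + fn) * (tp + fp))
  mcc <- safe_div(tn * tp - fn * fp, mcc_den)
  f1 <- safe_div(2 * tp, 2 * tp + fp + fn)
  if (degenerate) {
    warning("degenerate 0/0 denominator in metrics; affected values set to 0",
            call. = FALSE)
  }
  structure(list(acc = acc, sn = sn, sp = sp, mcc = mcc, f1 = f1,
                 counts = counts, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4L, ...) {
  cat(sprintf("ACC %.*f  SN %.*f  SP %.*f  MCC %.*f  F1 %.*f\n",
              digits, x$acc, digits, x$sn, digits, x$sp,
              digits, x$mcc, digits, x$f1))
  invisible(x)
}

# Stratified fold assignment with global fold sizes differing by at most 1:
# class-0 remainder folds are filled from fold 1 forward, class-1 from fold
# k backward, so the extras never stack on the same fold unless every fold
# receives one.
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  set.seed(seed)
  folds <- integer(n)
  idx0 <- sample(which(labels == 0L))
  idx1 <- sample(which(labels == 1L))
  folds[idx0] <- rep_len(seq_len(k), length(idx0))
  folds[idx1] <- rep_len(rev(seq_len(k)), length(idx1))
  folds
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the dataset into k near-equal stratified folds and evaluates the
#' SMOTE -> variational compressor -> gradient-boosted-tree pipeline on each
#' held-out fold. Two orderings of the oversampling step are provided:
#'
#' * `mode = "paper"` rebalances the whole dataset once, before the fold
#'   split, reproducing the published protocol. Synthetic points then share
#'   parents across folds, which leaks minority-neighborhood information
#'   into validation scores.
#' * `mode = "fold-safe"` applies SMOTE inside each training fold only, so
#'   validation folds contain no synthetic points and no information from
#'   held-out rows.
#'
#' Within each fold the compressor is trained with the multi-run MCC-based
#' selection of [vfc_select()] whenever `config$vfc$n_runs > 1`, and with a
#' single [vfc_fit()] otherwise.
#'
#' @param dataset A [labeled_dataset()] of raw (un-resampled) features.
#' @param k Number of folds (default 5).
#' @param config A [pipeline_config()] carrying the SMOTE, compressor and
#'   classifier settings; fold f derives its seeds from `config$seed + f`.
#' @param mode `"fold-safe"` (default) or `"paper"`.
#' @return A list of class `cv_report`: `per_fold` (data frame, one row per
#'   fold, columns acc/sn/sp/mcc/f1), `averages` (their arithmetic means),
#'   `mode` and `k`.
#' @export
kfold_cv <- function(dataset, k = 5L, config = pipeline_config(),
                     mode = c("fold-safe", "paper")) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  mode <- match.arg(mode)
  k <- as.integer(k)

  if (mode == "paper") {
    sm <- config$smote; sm$seed <- config$seed
    dataset <- smote_oversample(dataset, sm)
  }
  folds <- stratified_folds(dataset$labels, k, seed = config$seed)

  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    train <- labeled_dataset(dataset$ids[tr],
                             dataset$features[tr, , drop = FALSE],
                             dataset$labels[tr])
    if (mode == "fold-safe") {
      sm <- config$smote; sm$seed <- config$seed + f
      train <- smote_oversample(train, sm)
    }
    vcfg <- config$vfc
    vcfg$seed <- config$seed + f
    gp <- config$gbt; gp$seed <- config$seed + f
    vfc <- if (vcfg$n_runs > 1L) {
      vfc_select(train, vcfg,
                 downstream_trainer = function(x, l) gbt_train(x, l, gp))$model
    } else {
      vfc_fit(train, vcfg)
    }
    z_train <- vfc_transform(vfc, train$features)
    z_val <- vfc_transform(vfc, dataset$features[va, , drop = FALSE])
    clf <- gbt_train(z_train, train$labels, gp)
    pred <- predict(clf, z_val, type = "label")
    m <- compute_metrics(confusion_counts(dataset$labels[va], pred))
    rows[[f]] <- data.frame(fold = f, acc = m$acc, sn = m$sn, sp = m$sp,
                            mcc = m$mcc, f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  averages <- colMeans(per_fold[, c("acc", "sn", "sp", "mcc", "f1")])
  structure(list(per_fold = per_fold, averages = averages, mode = mode, k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4L, ...) {
  cat("Stratified ", x$k, "-fold cross-validation (", x$mode, " mode)\n", sep = "")
  tab <- rbind(x$per_fold[, -1L], Average = x$averages)
  rownames(tab) <- c(paste0("fold ", x$per_fold$fold), "Average")
  print(round(tab, digits))
  invisible(x)
}

#' Write a cross-validation report as a CSV table
#'
#' One row per fold plus an `Average` row; columns ACC, SN, SP, MCC, F1 as
#' percentages.
#'
#' @param report A [kfold_cv()] report.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_table <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  tab <- rbind(report$per_fold[, c("acc", "sn", "sp", "mcc", "f1")],
               report$averages)
  tab <- round(100 * tab, 2L)
  out <- data.frame(Times = c(as.character(report$per_fold$fold), "Average"),
                    ACC = tab$acc, SN = tab$sn, SP = tab$sp,
                    MCC = tab$mcc, F1 = tab$f1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
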