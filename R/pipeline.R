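#' Full pipeline configuration
#'
#' Bundles the per-stage settings (SMOTE, variational compressor,
#' gradient-boosted trees, cross-validation), the background frequencies
#' and the motif convention under a single master seed. Stage seeds are
#' derived from `seed` by the consumers ([kfold_cv()], [run_train()]).
#'
#' @param seed Master integer seed.
#' @param smote A [smote_config()].
#' @param vfc A [vfc_config()].
#' @param gbt A [gbt_params()].
#' @param cv List with elements `k` and `mode` (`"paper"` or `"fold-safe"`).
#' @param background_frequencies Positive 20-vector, canonical order.
#' @param motif `"bab"` or `"aba"` (see [motif_feature()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            smote = smote_config(seed = seed),
                            vfc = vfc_config(seed = seed),
                            gbt = gbt_params(seed = seed),
                            cv = list(k = 5L, mode = "paper"),
                            background_frequencies = default_background_frequencies(),
                            motif = c("bab", "aba")) {
  motif <- match.arg(motif)
  stopifnot(inherits(smote, "smote_config"), inherits(vfc, "vfc_config"),
            inherits(gbt, "gbt_params"), cv$k >= 2L,
            cv$mode %in% c("paper", "fold-safe"))
  structure(list(seed = as.integer(seed), smote = smote, vfc = vfc, gbt = gbt,
                 cv = cv,
                 background_frequencies = validate_background_frequencies(background_frequencies),
                 motif = motif),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' The JSON layout mirrors the nested structure of [pipeline_config()];
#' omitted keys fall back to the defaults, so a partial config overriding
#' e.g. only `vfc.lambda` is valid.
#'
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()];
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L
  merge_args <- function(defaults, overrides) {
    if (!is.null(overrides)) defaults[names(overrides)] <- overrides
    defaults
  }
  sm <- merge_args(list(m_neighbors = 5L, target_ratio = 1, seed = seed), raw$smote)
  vf <- merge_args(as.list(formals(vfc_config)), raw$vfc)
  vf$hidden_dims <- eval(vf$hidden_dims)
  vf$seed <- if (is.null(raw$vfc$seed)) seed else as.integer(raw$vfc$seed)
  gb <- merge_args(list(n_trees = 300L, learning_rate = 0.1, max_depth = 4L,
                        gamma = 0, reg_lambda = 1, seed = seed), raw$gbt)
  cv <- merge_args(list(k = 5L, mode = "paper"), raw$cv)
  bf <- if (is.null(raw$background_frequencies)) default_background_frequencies()
        else raw$background_frequencies
  motif <- if (is.null(raw$motif)) "bab" else raw$motif
  pipeline_config(seed = seed,
                  smote = do.call(smote_config, sm[c("m_neighbors", "target_ratio", "seed")]),
                  vfc = do.call(vfc_config, vf),
                  gbt = do.call(gbt_params, gb),
                  cv = cv, background_frequencies = bf, motif = motif)
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  payload <- list(seed = config$seed, smote = unclass(config$smote),
                  vfc = unclass(config$vfc), gbt = unclass(config$gbt),
                  cv = config$cv,
                  background_frequencies = unname(config$background_frequencies),
                  motif = config$motif)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

log_line <- function(log_path, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n", sep = "",
      file = log_path, append = TRUE)
}

#' Train the full classification pipeline
#'
#' Runs extract (473 features) -> SMOTE rebalancing -> multi-run
#' variational compression with MCC selection -> gradient-boosted-tree
#' training on the latent features, and writes a plain-text model bundle
#' (`vfc.json`, `gbt.json`, `config.json`, `manifest.json`) plus a training
#' log under `out_dir`.
#'
#' @param pssm_dir,ss2_dir,labels_file Inputs as in [extract_dataset()].
#' @param config A [pipeline_config()].
#' @param out_dir Bundle output directory (created if needed).
#' @return Invisibly, a list with the trained `vfc` selection, `gbt`
#'   classifier, `bundle_dir` and the stage sample counts.
#' @export
run_train <- function(pssm_dir, ss2_dir, labels_file,
                      config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "train.log")
  stage <- "extract"
  result <- tryCatch({
    dataset <- extract_dataset(pssm_dir, ss2_dir, labels_file,
                               bf = config$background_frequencies,
                               motif = config$motif)
    log_line(log_path, "extract: ", nrow(dataset$features), " x ",
             ncol(dataset$features), " (seed ", config$seed, ")")

    stage <- "smote"
    sm <- config$smote; sm$seed <- config$seed
    balanced <- smote_oversample(dataset, sm)
    log_line(log_path, "smote: ", nrow(balanced$features), " x ",
             ncol(balanced$features))

    stage <- "vfc"
    vcfg <- config$vfc; vcfg$seed <- config$seed
    sel <- vfc_select(balanced, vcfg,
                      downstream_trainer = function(f, l) gbt_train(f, l, config$gbt))
    latent <- vfc_transform(sel$model, balanced$features)
    log_line(log_path, "vfc: ", nrow(latent), " x ", ncol(latent),
             "; run MCCs ", paste(round(sel$report$val_mcc, 4L), collapse = ", "))

    stage <- "gbt"
    gp <- config$gbt; gp$seed <- config$seed
    clf <- gbt_train(latent, balanced$labels, gp)

    stage <- "serialize"
    vfc_save(sel$model, file.path(out_dir, "vfc.json"))
    xgboost::xgb.save(clf$booster, file.path(out_dir, "gbt.json"))
    write_pipeline_config(config, file.path(out_dir, "config.json"))
    manifest <- list(seed = config$seed,
                     n_input = length(dataset$ids),
                     n_after_smote = length(balanced$ids),
                     n_features = ncol(dataset$features),
                     latent_dim = ncol(latent),
                     selection = sel$report,
                     package_version = as.character(utils::packageVersion("antioxpred")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    log_line(log_path, "bundle written to ", normalizePath(out_dir))
    list(vfc = sel, gbt = clf, bundle_dir = out_dir,
         counts = list(input = length(dataset$ids),
                       after_smote = length(balanced$ids),
                       latent_dim = ncol(latent)))
  }, error = function(e) {
    log_line(log_path, "ERROR in stage '", stage, "': ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Predict with a trained pipeline bundle
#'
#' Loads the bundle written by [run_train()], extracts features for every
#' `<id>.pssm` / `<id>.ss2` pair found in the input directories, compresses
#' them with the stored VFC and scores them with the stored classifier.
#'
#' @param bundle_dir Directory produced by [run_train()].
#' @param pssm_dir,ss2_dir Profile directories.
#' @param out_csv Optional path; when given, a CSV `id,prob,label` is
#'   written.
#' @return Data frame with columns `id`, `prob`, `label`.
#' @export
run_predict <- function(bundle_dir, pssm_dir, ss2_dir, out_csv = NULL) {
  needed <- file.path(bundle_dir, c("vfc.json", "gbt.json", "config.json"))
  if (!all(file.exists(needed))) {
    stop("bundle at '", bundle_dir, "' is missing: ",
         paste(basename(needed[!file.exists(needed)]), collapse = ", "),
         call. = FALSE)
  }
  config <- read_pipeline_config(file.path(bundle_dir, "config.json"))
  vfc <- vfc_load(file.path(bundle_dir, "vfc.json"))
  booster <- xgboost::xgb.load(file.path(bundle_dir, "gbt.json"))

  ids <- sort(intersect(
    sub("\\.pssm$", "", list.files(pssm_dir, pattern = "\\.pssm$")),
    sub("\\.ss2$", "", list.files(ss2_dir, pattern = "\\.ss2$"))))
  if (length(ids) == 0L) {
    out <- data.frame(id = character(0), prob = numeric(0), label = integer(0))
  } else {
    feats <- matrix(NA_real_, length(ids), vfc$config$input_dim)
    for (i in seq_along(ids)) {
      profile <- read_pssm(file.path(pssm_dir, paste0(ids[i], ".pssm")))
      track <- read_ss2(file.path(ss2_dir, paste0(ids[i], ".ss2")))
      feats[i, ] <- extract_features(profile, track,
                                     bf = config$background_frequencies,
                                     motif = config$motif)
    }
    z <- vfc_transform(vfc, feats)
    prob <- predict(booster, xgboost::xgb.DMatrix(z))
    out <- data.frame(id = ids, prob = prob, label = as.integer(prob >= 0.5))
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
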