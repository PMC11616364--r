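#' Variational feature compressor configuration
#'
#' The compressor is a dense ReLU encoder with a Gaussian latent layer
#' trained on the variational information-bottleneck bound: classification
#' negative log-likelihood of the label given a reparameterized latent
#' sample, plus `lambda` times the closed-form KL divergence of the
#' diagonal-Gaussian posterior from the standard-normal prior.
#'
#' @param input_dim Input feature dimensionality (473 for the full vector).
#' @param hidden_dims Integer vector of encoder hidden-layer widths.
#' @param latent_dim Latent dimensionality K (default 15).
#' @param lambda Non-negative information-bottleneck trade-off weight.
#' @param epochs,batch_size,learning_rate Optimization settings (Adam).
#' @param n_runs Number of independently seeded candidate models generated
#'   by [vfc_select()].
#' @param seed Integer seed; run r of a multi-run selection uses `seed + r`.
#' @param val_fraction Fraction held out for MCC-based selection.
#' @return An object of class `vfc_config`.
#' @export
vfc_config <- function(input_dim = 473L, hidden_dims = c(256L, 64L),
                       latent_dim = 15L, lambda = 1e-3, epochs = 200L,
                       batch_size = 64L, learning_rate = 1e-3,
                       n_runs = 3L, seed = 1L, val_fraction = 0.2) {
  stopifnot(latent_dim >= 1L, lambda >= 0, n_runs >= 1L,
            val_fraction > 0, val_fraction < 1,
            epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 lambda = lambda, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "vfc_config")
}

#' Closed-form KL divergence of a diagonal Gaussian from the standard normal
#'
#' For `N(mu, diag(sigma^2))` against `N(0, I)`:
#' `0.5 * sum(sigma^2 + mu^2 - 1 - log(sigma^2))`, per row when matrices
#' are supplied. Always non-negative; zero iff `mu = 0, sigma = 1`.
#'
#' @param mu,sigma Numeric vectors, or matrices with one row per sample.
#' @return Numeric vector of per-sample KL divergences (nats).
#' @export
#' @examples
#' gaussian_kl(1, 2)   # 0.5 * (4 + 1 - 1 - log(4))
gaussian_kl <- function(mu, sigma) {
  mu <- rbind(mu); sigma <- rbind(sigma)
  stopifnot(all(dim(mu) == dim(sigma)), all(sigma > 0))
  unname(rowSums(0.5 * (sigma^2 + mu^2 - 1 - 2 * log(sigma))))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

new_dense <- function(n_in, n_out) {
  # He-normal initialization suited to ReLU activations
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

vfc_init_params <- function(config) {
  dims <- c(config$input_dim, config$hidden_dims)
  hidden <- lapply(seq_along(config$hidden_dims),
                   function(i) new_dense(dims[i], dims[i + 1L]))
  last <- dims[length(dims)]
  list(hidden = hidden,
       mean_head = new_dense(last, config$latent_dim),
       scale_head = new_dense(last, config$latent_dim),
       class_head = new_dense(config$latent_dim, 1L))
}

# forward pass through the encoder trunk and heads; X already standardized
vfc_forward <- function(params, X) {
  acts <- list(X)
  pre <- list()
  h <- X
  for (i in seq_along(params$hidden)) {
    a <- sweep(h %*% params$hidden[[i]]$W, 2L, params$hidden[[i]]$b, `+`)
    pre[[i]] <- a
    h <- pmax(a, 0)
    acts[[i + 1L]] <- h
  }
  mu <- sweep(h %*% params$mean_head$W, 2L, params$mean_head$b, `+`)
  s_pre <- sweep(h %*% params$scale_head$W, 2L, params$scale_head$b, `+`)
  list(acts = acts, pre = pre, h = h, mu = mu, s_pre = s_pre,
       sigma = softplus(s_pre))
}

class_logit <- function(params, z) {
  drop(z %*% params$class_head$W) + params$class_head$b
}

standardize_apply <- function(std, X) {
  sweep(sweep(X, 2L, std$center, `-`), 2L, std$scale, `/`)
}

#' Information-bottleneck training loss of a VFC model
#'
#' Evaluates the negated Monte-Carlo variational bound on a batch: the mean
#' classification negative log-likelihood `-log t(c | p)` with the latent
#' sampled by reparameterization `z = E(r) + eps * D(r)`,
#' `eps ~ N(0, I)`, plus `lambda` times the mean closed-form KL divergence
#' of the posterior `q(p | r)` from the standard-normal prior `s(p)`.
#'
#' @param features Numeric n x d matrix (raw scale; the model's stored
#'   standardizer is applied).
#' @param labels 0/1 vector of length n.
#' @param model A [vfc_fit()] model.
#' @return A list with `loss`, `nll`, `kl` (all batch means) and the
#'   sampled `z`.
#' @export
vfc_loss <- function(features, labels, model) {
  stopifnot(inherits(model, "vfc_model"))
  X <- standardize_apply(model$standardizer, as.matrix(features))
  fwd <- vfc_forward(model$params, X)
  eps <- matrix(stats::rnorm(length(fwd$mu)), nrow(fwd$mu), ncol(fwd$mu))
  z <- fwd$mu + eps * fwd$sigma
  logit <- class_logit(model$params, z)
  nll <- mean(softplus(logit) - labels * logit)
  kl <- mean(gaussian_kl(fwd$mu, fwd$sigma))
  loss <- nll + model$config$lambda * kl
  if (!is.finite(loss)) {
    stop("non-finite VFC loss (nll = ", format(nll), ", kl = ", format(kl), ")",
         call. = FALSE)
  }
  list(loss = loss, nll = nll, kl = kl, z = z)
}

# one reparameterized gradient step on a mini-batch; returns grads as a
# flat list mirroring the parameter layout
vfc_gradients <- function(params, X, y, lambda) {
  n <- nrow(X)
  fwd <- vfc_forward(params, X)
  eps <- matrix(stats::rnorm(length(fwd$mu)), n, ncol(fwd$mu))
  z <- fwd$mu + eps * fwd$sigma
  logit <- class_logit(params, z)
  p <- stats::plogis(logit)

  nll <- mean(softplus(logit) - y * logit)
  kl <- mean(gaussian_kl(fwd$mu, fwd$sigma))
  loss <- nll + lambda * kl

  dlogit <- matrix((p - y) / n, ncol = 1L)
  g_class <- list(W = t(z) %*% dlogit, b = sum(dlogit))
  dz <- dlogit %*% t(params$class_head$W)
  dmu <- dz + (lambda / n) * fwd$mu
  dsigma <- dz * eps + (lambda / n) * (fwd$sigma - 1 / fwd$sigma)
  ds_pre <- dsigma * stats::plogis(fwd$s_pre)

  g_mean <- list(W = t(fwd$h) %*% dmu, b = colSums(dmu))
  g_scale <- list(W = t(fwd$h) %*% ds_pre, b = colSums(ds_pre))
  dh <- dmu %*% t(params$mean_head$W) + ds_pre %*% t(params$scale_head$W)

  g_hidden <- vector("list", length(params$hidden))
  for (i in rev(seq_along(params$hidden))) {
    da <- dh * (fwd$pre[[i]] > 0)
    g_hidden[[i]] <- list(W = t(fwd$acts[[i]]) %*% da, b = colSums(da))
    dh <- da %*% t(params$hidden[[i]]$W)
  }
  list(grads = list(hidden = g_hidden, mean_head = g_mean,
                    scale_head = g_scale, class_head = g_class),
       loss = loss, nll = nll, kl = kl)
}

# Adam over the nested parameter list
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  walk(params, grads, state$m, state$v)
}

zeros_like <- function(p) {
  if (is.list(p)) lapply(p, zeros_like) else p * 0
}

#' Fit the variational feature compressor
#'
#' Standardizes the inputs to zero mean / unit variance (statistics stored
#' in the model), then minimizes the information-bottleneck loss
#' ([vfc_loss()]) by mini-batch Adam with reparameterized latent sampling.
#' Fully deterministic under a fixed `config$seed`.
#'
#' @param dataset A [labeled_dataset()] with both classes present, or a
#'   numeric matrix (then supply `labels`).
#' @param config A [vfc_config()] whose `input_dim` matches the features.
#' @param labels 0/1 labels when `dataset` is a bare matrix.
#' @return An object of class `vfc_model` with elements `params`,
#'   `standardizer`, `config` and `history` (per-epoch mean loss/nll/kl).
#' @export
vfc_fit <- function(dataset, config = vfc_config(), labels = NULL) {
  if (inherits(dataset, "labeled_dataset")) {
    X <- dataset$features
    y <- dataset$labels
  } else {
    X <- as.matrix(dataset)
    y <- as.integer(labels)
  }
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  if (ncol(X) != config$input_dim) {
    stop("feature dimensionality ", ncol(X), " does not match config input_dim ",
         config$input_dim, call. = FALSE)
  }
  n <- nrow(X)

  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  std <- list(center = center, scale = scale)
  Xs <- standardize_apply(std, X)

  set.seed(config$seed)
  params <- vfc_init_params(config)
  opt <- list(m = zeros_like(params), v = zeros_like(params))
  t_step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        nll = numeric(0), kl = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- ep_nll <- ep_kl <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      g <- vfc_gradients(params, Xs[idx, , drop = FALSE], y[idx], config$lambda)
      if (!is.finite(g$loss)) {
        stop("VFC training diverged at epoch ", epoch,
             " (non-finite loss); reduce learning_rate", call. = FALSE)
      }
      t_step <- t_step + 1L
      upd <- adam_update(params, g$grads, opt, config$learning_rate, t_step)
      params <- upd$p
      opt <- list(m = upd$m, v = upd$v)
      w <- length(idx) / n
      ep_loss <- ep_loss + w * g$loss
      ep_nll <- ep_nll + w * g$nll
      ep_kl <- ep_kl + w * g$kl
    }
    history[epoch, ] <- list(epoch, ep_loss, ep_nll, ep_kl)
  }

  structure(list(params = params, standardizer = std, config = config,
                 history = history),
            class = "vfc_model")
}

#' @export
print.vfc_model <- function(x, ...) {
  cat("<vfc_model> ", x$config$input_dim, " -> [",
      paste(x$config$hidden_dims, collapse = ", "), "] -> ",
      x$config$latent_dim, " latent; lambda = ", x$config$lambda, "\n", sep = "")
  invisible(x)
}

#' Compress features to the latent representation
#'
#' Deterministic transform: returns the posterior means `E(r)` per sample
#' (no sampling at inference time), giving stable inputs for downstream
#' tree training.
#'
#' @param model A [vfc_fit()] model.
#' @param features Numeric n x d matrix on the raw feature scale.
#' @return Numeric n x K matrix of latent means.
#' @export
vfc_transform <- function(model, features) {
  stopifnot(inherits(model, "vfc_model"))
  X <- as.matrix(features)
  if (ncol(X) != model$config$input_dim) {
    stop("feature dimensionality ", ncol(X), " does not match the model's input_dim ",
         model$config$input_dim, call. = FALSE)
  }
  fwd <- vfc_forward(model$params, standardize_apply(model$standardizer, X))
  fwd$mu
}

#' Multi-run VFC training with MCC-based selection
#'
#' Weight initialization and latent sampling make each training run
#' stochastic, so several candidate compressors are generated (run r seeded
#' with `seed + r`) and the one whose latent features give the highest
#' validation MCC with the downstream classifier is kept (ties go to the
#' lower run index).
#'
#' @param dataset A [labeled_dataset()].
#' @param config A [vfc_config()]; `n_runs` and `val_fraction` control the
#'   selection.
#' @param downstream_trainer Function `(features, labels)` returning an
#'   object whose `predict(object, newdata, type = "label")` yields 0/1
#'   labels. Defaults to gradient-boosted trees with [gbt_params()]
#'   defaults.
#' @return A list of class `vfc_selection`: `model` (the winning
#'   `vfc_model`) and `report` (data frame of per-run seeds and validation
#'   MCCs).
#' @export
vfc_select <- function(dataset, config = vfc_config(), downstream_trainer = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(downstream_trainer)) {
    downstream_trainer <- function(features, labels) {
      gbt_train(features, labels, gbt_params(seed = config$seed))
    }
  }
  n <- nrow(dataset$features)
  set.seed(config$seed)
  val_idx <- sort(unlist(lapply(split(seq_len(n), dataset$labels), function(idx) {
    sample(idx, max(1L, round(config$val_fraction * length(idx))))
  })))
  train_idx <- setdiff(seq_len(n), val_idx)

  mccs <- numeric(config$n_runs)
  models <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r
    model <- vfc_fit(dataset$features[train_idx, , drop = FALSE], cfg_r,
                     labels = dataset$labels[train_idx])
    z_train <- vfc_transform(model, dataset$features[train_idx, , drop = FALSE])
    z_val <- vfc_transform(model, dataset$features[val_idx, , drop = FALSE])
    clf <- downstream_trainer(z_train, dataset$labels[train_idx])
    pred <- predict(clf, z_val, type = "label")
    counts <- confusion_counts(dataset$labels[val_idx], pred)
    mccs[r] <- compute_metrics(counts)$mcc
    models[[r]] <- model
  }
  best <- which.max(mccs)   # first index on ties
  structure(list(model = models[[best]],
                 report = data.frame(run = seq_len(config$n_runs),
                                     seed = config$seed + seq_len(config$n_runs),
                                     val_mcc = mccs,
                                     selected = seq_len(config$n_runs) == best)),
            class = "vfc_selection")
}

#' Save / load a VFC model as JSON
#'
#' Serializes the full parameter set, standardizer and configuration in a
#' plain-text JSON document so a trained compressor can be shipped and
#' reloaded without binary artifacts.
#'
#' @param model A `vfc_model`.
#' @param path Output path.
#' @return `vfc_save()` returns `path` invisibly; `vfc_load()` the model.
#' @export
vfc_save <- function(model, path) {
  stopifnot(inherits(model, "vfc_model"))
  payload <- list(params = model$params, standardizer = model$standardizer,
                  config = unclass(model$config))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname vfc_save
#' @export
vfc_load <- function(path) {
  if (!file.exists(path)) stop("VFC model file not found: ", path, call. = FALSE)
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  as_dense <- function(l) list(W = as.matrix(l$W), b = as.numeric(l$b))
  params <- list(hidden = lapply(payload$params$hidden, as_dense),
                 mean_head = as_dense(payload$params$mean_head),
                 scale_head = as_dense(payload$params$scale_head),
                 class_head = as_dense(payload$params$class_head))
  cfg <- payload$config
  config <- vfc_config(input_dim = cfg$input_dim, hidden_dims = cfg$hidden_dims,
                       latent_dim = cfg$latent_dim, lambda = cfg$lambda,
                       epochs = cfg$epochs, batch_size = cfg$batch_size,
                       learning_rate = cfg$learning_rate, n_runs = cfg$n_runs,
                       seed = cfg$seed, val_fraction = cfg$val_fraction)
  structure(list(params = params,
                 standardizer = list(center = as.numeric(payload$standardizer$center),
                                     scale = as.numeric(payload$standardizer$scale)),
                 config = config, history = NULL),
            class = "vfc_model")
}
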