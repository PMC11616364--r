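#' SMOTE configuration
#'
#' @param m_neighbors Number of nearest minority neighbors considered per
#'   parent point (classic SMOTE default 5).
#' @param target_ratio Desired minority:majority ratio after oversampling
#'   (default 1, i.e. fully balanced).
#' @param seed Integer seed controlling parent/neighbor/interpolation draws.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(m_neighbors = 5L, target_ratio = 1, seed = 1L) {
  m_neighbors <- as.integer(m_neighbors)
  if (m_neighbors < 1L) stop("m_neighbors must be >= 1", call. = FALSE)
  if (!is.numeric(target_ratio) || target_ratio <= 0) {
    stop("target_ratio must be > 0", call. = FALSE)
  }
  structure(list(m_neighbors = m_neighbors, target_ratio = target_ratio,
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' SMOTE minority oversampling
#'
#' Rebalances a two-class dataset by appending synthetic minority points.
#' Each synthetic point is `x + u * (x_nn - x)` where `x` is a minority
#' sample drawn uniformly with replacement, `x_nn` one of its `m_neighbors`
#' nearest minority neighbors (Euclidean distance, self excluded) drawn
#' uniformly, and `u ~ U[0, 1]`. Original rows are retained unchanged and
#' first; the synthetic count is chosen so that the final
#' minority/majority ratio equals `target_ratio` (rounded to the nearest
#' integer count).
#'
#' @param dataset A [labeled_dataset()] containing both classes.
#' @param config A [smote_config()].
#' @return A [labeled_dataset()]; synthetic rows have ids `smote_<k>` and
#'   the minority label. Returned unchanged when no synthetic points are
#'   needed.
#' @export
smote_oversample <- function(dataset, config = smote_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"), inherits(config, "smote_config"))
  n_per_class <- table(factor(dataset$labels, levels = c(0L, 1L)))
  if (any(n_per_class == 0L)) {
    stop("SMOTE requires both classes to be present", call. = FALSE)
  }
  minority_label <- if (n_per_class[["1"]] <= n_per_class[["0"]]) 1L else 0L
  n_min <- as.integer(n_per_class[[as.character(minority_label)]])
  n_maj <- as.integer(sum(n_per_class) - n_min)
  n_syn <- as.integer(round(config$target_ratio * n_maj)) - n_min
  if (n_syn <= 0L) return(dataset)
  if (n_min <= config$m_neighbors) {
    stop("minority class has ", n_min, " samples but m_neighbors = ",
         config$m_neighbors, "; choose a smaller M", call. = FALSE)
  }

  min_idx <- which(dataset$labels == minority_label)
  X <- dataset$features[min_idx, , drop = FALSE]
  # nearest-neighbor table within the minority class, self excluded
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(config$m_neighbors)]))

  set.seed(config$seed)
  parents <- sample.int(n_min, n_syn, replace = TRUE)
  nb_pick <- sample.int(config$m_neighbors, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  neighbors <- nn[cbind(parents, nb_pick)]
  syn <- X[parents, , drop = FALSE] +
    u * (X[neighbors, , drop = FALSE] - X[parents, , drop = FALSE])

  labeled_dataset(c(dataset$ids, paste0("smote_", seq_len(n_syn))),
                  rbind(dataset$features, syn),
                  c(dataset$labels, rep(minority_label, n_syn)))
}
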