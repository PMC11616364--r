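state_chars <- function(states) {
  st <- strsplit(states, "")[[1]]
  if (!all(st %in% SS_STATES)) {
    stop("states string must contain only H, E, C", call. = FALSE)
  }
  st
}

#' Composition-moment features of the state sequence
#'
#' For each state X in (H, E, C), the sum of the 1-based positions at which
#' X occurs, normalized by L(L-1). Position weighting makes the feature
#' sensitive to where in the chain a state concentrates, not only how often
#' it occurs.
#'
#' @param states Character string over `{H,E,C}` of length >= 2.
#' @return Numeric vector `c(D_H, D_E, D_C)`.
#' @export
#' @examples
#' cmv_state_features("HHHEEC")   # c(6, 9, 6) / 30
cmv_state_features <- function(states) {
  st <- state_chars(states)
  L <- length(st)
  if (L < 2L) stop("state sequence must have length >= 2 (L(L-1) normalization)",
                   call. = FALSE)
  denom <- L * (L - 1)
  pos <- seq_len(L)
  c(D_H = sum(pos[st == "H"]) / denom,
    D_E = sum(pos[st == "E"]) / denom,
    D_C = sum(pos[st == "C"]) / denom)
}

#' Normalized maximum run lengths of strand and helix
#'
#' @param states Character string over `{H,E,C}`.
#' @return Numeric vector `c(D_ME, D_MH)`: longest E run / L and longest
#'   H run / L.
#' @export
max_run_features <- function(states) {
  st <- state_chars(states)
  L <- length(st)
  if (L < 1L) stop("empty state sequence", call. = FALSE)
  r <- rle(st)
  max_run <- function(x) if (any(r$values == x)) max(r$lengths[r$values == x]) else 0L
  c(D_ME = max_run("E") / L, D_MH = max_run("H") / L)
}

#' Strand-helix-strand motif density
#'
#' Collapses each maximal helix run to a single \eqn{\alpha} symbol and each
#' maximal strand run to a single \eqn{\beta} symbol, drops coil entirely,
#' and counts overlapping occurrences of the chosen three-symbol motif in
#' the resulting fragment sequence, normalized by L-2. The default motif
#' `"bab"` (\eqn{\beta\alpha\beta}) discriminates alpha/beta from
#' alpha+beta folds; `"aba"` counts \eqn{\alpha\beta\alpha} instead.
#'
#' @param states Character string over `{H,E,C}` of length >= 3.
#' @param motif `"bab"` (default) or `"aba"`.
#' @return Motif count / (L - 2).
#' @export
#' @examples
#' motif_feature("EEHHEE")   # fragments b a b -> 1 / 4
motif_feature <- function(states, motif = c("bab", "aba")) {
  motif <- match.arg(motif)
  st <- state_chars(states)
  L <- length(st)
  if (L < 3L) stop("state sequence must have length >= 3 (L-2 normalization)",
                   call. = FALSE)
  runs <- rle(st)$values
  frag <- c(H = "a", E = "b")[runs[runs != "C"]]
  n <- length(frag)
  if (n < 3L) return(0)
  pat <- strsplit(motif, "")[[1]]
  count <- sum(frag[1:(n - 2L)] == pat[1] &
               frag[2:(n - 1L)] == pat[2] &
               frag[3:n] == pat[3])
  count / (L - 2)
}

#' Global state-probability features
#'
#' Column means of the L x 3 structure probability matrix, in (C, H, E)
#' order: the mean predicted probability of each state over the chain.
#'
#' @param probs Numeric L x 3 matrix with columns (C, H, E).
#' @return Numeric vector of length 3.
#' @export
global_probability_features <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L) stop("empty probability matrix", call. = FALSE)
  if (ncol(probs) != 3L) stop("probability matrix must have 3 columns", call. = FALSE)
  out <- colMeans(probs)
  names(out) <- paste0("global_", SS_STATES)
  out
}

# Contiguous 8-way row partition; earlier blocks absorb the remainder rows.
local_block_sizes <- function(L) {
  base <- L %/% 8L
  base + as.integer(seq_len(8L) <= L %% 8L)
}

#' Local state-probability features
#'
#' Partitions the probability matrix rows into 8 contiguous blocks (sizes
#' differing by at most one; earlier blocks take the extra rows when L is
#' not a multiple of 8) and reports each block's 3 column means, giving 24
#' values ordered block 1 (C,H,E), block 2 (C,H,E), ..., block 8.
#'
#' @param probs Numeric L x 3 matrix with columns (C, H, E), L >= 8.
#' @return Numeric vector of length 24.
#' @export
local_probability_features <- function(probs) {
  probs <- as.matrix(probs)
  L <- nrow(probs)
  if (L < 8L) stop("local features require at least 8 residues, got ", L, call. = FALSE)
  if (ncol(probs) != 3L) stop("probability matrix must have 3 columns", call. = FALSE)
  sizes <- local_block_sizes(L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  out <- numeric(24L)
  for (b in seq_len(8L)) {
    out[(b - 1L) * 3L + 1:3] <- colMeans(probs[starts[b]:ends[b], , drop = FALSE])
  }
  names(out) <- paste0("local_", rep(seq_len(8L), each = 3L), rep(SS_STATES, 8L))
  out
}

#' Full 33-value secondary-structure feature block
#'
#' Concatenates the 6 state-sequence features (three composition moments,
#' two maximum-run lengths, one motif density), the 3 global probability
#' means and the 24 local block means.
#'
#' @param track An [ss_track()] with L >= 8.
#' @param motif Motif convention passed to [motif_feature()].
#' @return Numeric vector of length 33.
#' @export
ss_feature_block <- function(track, motif = c("bab", "aba")) {
  stopifnot(inherits(track, "ss_track"))
  motif <- match.arg(motif)
  c(cmv_state_features(track$states),
    max_run_features(track$states),
    D_motif = motif_feature(track$states, motif),
    global_probability_features(track$probs),
    local_probability_features(track$probs))
}
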