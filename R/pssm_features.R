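#' PSSM column means
#'
#' The first 20 PSSM-derived features: the mean substitution score toward
#' each of the 20 residue types over all positions, i.e. the per-column mean
#' of the L x 20 score matrix.
#'
#' @param profile A [pssm_profile()].
#' @return Named numeric vector of length 20 in canonical order.
#' @export
pssm_column_means <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (nrow(profile$scores) < 1L) stop("empty PSSM profile", call. = FALSE)
  colMeans(profile$scores)
}

#' Consensus sequence from a PSSM
#'
#' Each score is first passed through the background-weighted exponential
#' transform `a' = 2^(a * bf_j)`, and the residue maximizing the transformed
#' row is emitted. Ties are broken toward the first residue in canonical
#' order, making the consensus deterministic.
#'
#' @param profile A [pssm_profile()].
#' @param bf Background frequencies (positive 20-vector, canonical order);
#'   defaults to [default_background_frequencies()].
#' @return Consensus residue string of length L.
#' @export
consensus_sequence <- function(profile, bf = default_background_frequencies()) {
  stopifnot(inherits(profile, "pssm_profile"))
  bf <- validate_background_frequencies(bf)
  if (nrow(profile$scores) < 1L) stop("empty PSSM profile", call. = FALSE)
  a_prime <- 2^(sweep(profile$scores, 2L, bf, `*`))
  if (any(!is.finite(a_prime))) {
    stop("non-finite value in the 2^(score * bf) transform; ",
         "consider rescaling scores or background frequencies", call. = FALSE)
  }
  paste(AA_ALPHABET[apply(a_prime, 1L, which.max)], collapse = "")
}

#' Weighted 1-gram / 2-gram composition of the consensus sequence
#'
#' Computes the 420 n-gram features: single-residue frequencies
#' `O(P_i)/L` (20 values) and overlapping adjacent-pair frequencies
#' `O(P_i P_j)/L` (400 values, pair index row-major in canonical order),
#' combined with weights 20/420 and 400/420 respectively. The pair
#' denominator is L, so the raw pair frequencies sum to (L-1)/L.
#'
#' @param consensus Residue string of length >= 2 over the 20 standard letters.
#' @return Numeric vector of length 420: 20 weighted 1-gram values followed
#'   by 400 weighted 2-gram values.
#' @export
#' @examples
#' ngram_features("AAAA")[1]            # 20 * (4/4) / 420
ngram_features <- function(consensus) {
  stopifnot(is.character(consensus), length(consensus) == 1L)
  L <- nchar(consensus)
  if (L < 2L) stop("consensus sequence must have length >= 2 to form residue pairs",
                   call. = FALSE)
  idx <- match(strsplit(consensus, "")[[1]], AA_ALPHABET)
  if (any(is.na(idx))) stop("consensus contains a non-standard residue letter",
                            call. = FALSE)
  one <- tabulate(idx, nbins = 20L) / L
  pair_idx <- (idx[-L] - 1L) * 20L + idx[-1L]
  two <- tabulate(pair_idx, nbins = 400L) / L
  out <- c(20 * one / 420, 400 * two / 420)
  names(out) <- c(paste0("g1_", AA_ALPHABET),
                  paste0("g2_", rep(AA_ALPHABET, each = 20L), rep(AA_ALPHABET, 20L)))
  out
}

#' Full 440-value PSSM feature block
#'
#' Concatenates the 20 column means with the 420 weighted n-gram features of
#' the consensus sequence: `[column means | 1-gram | 2-gram]`.
#'
#' @inheritParams consensus_sequence
#' @return Numeric vector of length 440.
#' @export
pssm_feature_block <- function(profile, bf = default_background_frequencies()) {
  means <- pssm_column_means(profile)
  names(means) <- paste0("pssm_mean_", AA_ALPHABET)
  c(means, ngram_features(consensus_sequence(profile, bf)))
}
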