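# Canonical amino-acid column order used for all PSSM-derived features.
# File column orders are permuted onto this order on read.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters excluded from the benchmark construction: ambiguity codes and
# non-standard residues whose PSSM columns are undefined.
EXCLUDED_LETTERS <- c("B", "X", "Z", "O", "U", "J")

SS_STATES <- c("C", "H", "E")

#' Default amino-acid background frequencies
#'
#' Per-residue background frequencies in the canonical column order
#' `ACDEFGHIKLMNPQRSTVWY`, used to weight PSSM scores before taking the
#' per-row consensus residue. Defaults are overall SwissProt composition,
#' normalized to sum to 1; any positive 20-vector may be substituted
#' (e.g. frequencies estimated from a non-redundant PDB subset).
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' bf <- default_background_frequencies()
#' sum(bf)
default_background_frequencies <- function() {
  bf <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
          G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0965,
          M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
          S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292)
  bf / sum(bf)
}

validate_background_frequencies <- function(bf) {
  if (!is.numeric(bf) || length(bf) != 20L) {
    stop("background frequencies must be a numeric vector of length 20", call. = FALSE)
  }
  if (any(!is.finite(bf)) || any(bf <= 0)) {
    stop("background frequencies must be finite and strictly positive", call. = FALSE)
  }
  bf <- as.numeric(bf)
  names(bf) <- AA_ALPHABET
  bf
}
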