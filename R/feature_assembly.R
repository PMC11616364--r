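#' Index map of the 473-feature layout
#'
#' Named list of 1-based index ranges partitioning the full feature vector:
#' `pssm_means` (20), `ngram` (420), `ss_seq` (6), `ss_global` (3),
#' `ss_local` (24).
#'
#' @return Named list of integer vectors.
#' @export
feature_block_map <- function() {
  list(pssm_means = 1:20,
       ngram      = 21:440,
       ss_seq     = 441:446,
       ss_global  = 447:449,
       ss_local   = 450:473)
}

#' Extract the full 473-dimensional feature vector for one protein
#'
#' Concatenates the 440-value PSSM block and the 33-value secondary-structure
#' block for a matched profile/track pair describing the same chain.
#'
#' @param profile A [pssm_profile()].
#' @param track An [ss_track()] over the same chain (equal length).
#' @param bf Background frequencies for the consensus transform.
#' @param motif Motif convention, see [motif_feature()].
#' @return Numeric vector of length 473 with attribute `block_map`
#'   (see [feature_block_map()]).
#' @export
extract_features <- function(profile, track,
                             bf = default_background_frequencies(),
                             motif = c("bab", "aba")) {
  stopifnot(inherits(profile, "pssm_profile"), inherits(track, "ss_track"))
  motif <- match.arg(motif)
  Lp <- nchar(profile$sequence)
  Ls <- nchar(track$states)
  if (Lp != Ls) {
    stop("length mismatch for '", profile$record_id, "': PSSM has ", Lp,
         " residues, secondary-structure track has ", Ls, call. = FALSE)
  }
  out <- c(pssm_feature_block(profile, bf), ss_feature_block(track, motif))
  stopifnot(length(out) == 473L)
  attr(out, "block_map") <- feature_block_map()
  out
}

#' Batch-extract a labeled feature dataset from profile directories
#'
#' Reads `<id>.pssm` from `pssm_dir` and `<id>.ss2` from `ss2_dir` for every
#' id in the labels file, extracts the 473 features per record, and returns
#' the rows in labels-file order.
#'
#' @param pssm_dir Directory of PSI-BLAST ASCII PSSM files.
#' @param ss2_dir Directory of PSI-PRED ss2 files.
#' @param labels_file Two-column CSV `id,label` (1 = antioxidant).
#' @inheritParams extract_features
#' @return A [labeled_dataset()] with an n x 473 feature matrix.
#' @export
extract_dataset <- function(pssm_dir, ss2_dir, labels_file,
                            bf = default_background_frequencies(),
                            motif = c("bab", "aba")) {
  motif <- match.arg(motif)
  if (!file.exists(labels_file)) stop("labels file not found: ", labels_file, call. = FALSE)
  lab <- utils::read.csv(labels_file, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(lab))) {
    stop("labels file must have columns 'id' and 'label'", call. = FALSE)
  }
  if (anyDuplicated(lab$id)) {
    stop("duplicate ids in labels file: ",
         paste(unique(lab$id[duplicated(lab$id)]), collapse = ", "), call. = FALSE)
  }
  pssm_paths <- file.path(pssm_dir, paste0(lab$id, ".pssm"))
  ss2_paths <- file.path(ss2_dir, paste0(lab$id, ".ss2"))
  missing <- lab$id[!file.exists(pssm_paths) | !file.exists(ss2_paths)]
  if (length(missing) > 0L) {
    stop("missing PSSM and/or ss2 file for id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  feats <- matrix(NA_real_, nrow(lab), 473L)
  for (i in seq_len(nrow(lab))) {
    profile <- read_pssm(pssm_paths[i])
    track <- read_ss2(ss2_paths[i])
    feats[i, ] <- extract_features(profile, track, bf = bf, motif = motif)
  }
  colnames(feats) <- feature_column_names(473L)
  labeled_dataset(lab$id, feats, lab$label)
}
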