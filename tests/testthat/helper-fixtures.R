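# Shared fixture builders: everything is generated in code at test time.

make_profile <- function(scores, sequence = NULL, id = "prof") {
  scores <- as.matrix(scores)
  if (is.null(sequence)) sequence <- strrep("A", nrow(scores))
  pssm_profile(id, sequence, scores)
}

make_track <- function(states, probs = NULL, id = "trk") {
  L <- nchar(states)
  if (is.null(probs)) probs <- matrix(1 / 3, L, 3L)
  ss_track(id, states, probs)
}

random_profile <- function(L, seed = 1) {
  set.seed(seed)
  scores <- matrix(sample(-10:12, L * 20L, replace = TRUE), L, 20L)
  seq <- paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                        "M","N","P","Q","R","S","T","V","W","Y"),
                      L, replace = TRUE), collapse = "")
  make_profile(scores, seq)
}

random_track <- function(L, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(L * 3L, shape = 2), L, 3L)
  probs <- g / rowSums(g)
  states <- paste(c("C", "H", "E")[max.col(probs, ties.method = "first")],
                  collapse = "")
  make_track(states, probs)
}

# small labeled dataset with a linear class signal in the first `k` columns
signal_dataset <- function(n = 100, d = 20, k = 3, shift = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  y <- rep(c(0L, 1L), length.out = n)
  X[y == 1L, seq_len(k)] <- X[y == 1L, seq_len(k)] + shift
  labeled_dataset(sprintf("s%04d", seq_len(n)), X, y)
}

write_fasta_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# minimal PSI-BLAST ASCII layout with configurable column order
write_pssm_fixture <- function(scores, residues, aa_order, path = NULL) {
  if (is.null(path)) {
    path <- withr::local_tempfile(fileext = ".pssm",
                                  .local_envir = parent.frame())
  }
  lines <- c("",
             "Last position-specific scoring matrix computed, weighted observed percentages rounded down",
             paste0("          ", paste(sprintf("%4s", aa_order), collapse = "")))
  for (i in seq_len(nrow(scores))) {
    lines <- c(lines, paste0(sprintf("%5d %s ", i, residues[i]),
                             paste(sprintf("%4d", scores[i, ]), collapse = ""),
                             " ",
                             paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
                             "  0.00     0.00"))
  }
  writeLines(c(lines, ""), path)
  path
}

write_ss2_fixture <- function(rows, path = NULL) {
  if (is.null(path)) {
    path <- withr::local_tempfile(fileext = ".ss2", .local_envir = parent.frame())
  }
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V4.0)", "", rows), path)
  path
}
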