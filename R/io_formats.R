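#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and returns a plain data frame.
#' Sequence letters are upper-cased and wrapped lines concatenated. Records
#' with an empty sequence are rejected, as the downstream profile features
#' are undefined for them.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with character columns `id` and `sequence`, one row
#'   per record, in file order. The `id` is the header token up to the first
#'   whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA file '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stop("FASTA record(s) with empty sequence in '", path, "': ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Drop sequences containing excluded residue letters
#'
#' Removes records whose sequence contains any of the ambiguity or
#' non-standard letters B, X, Z, O, U, J, for which substitution-score
#' columns are undefined. Remaining records keep their input order.
#'
#' @param records Data frame with columns `id` and `sequence`
#'   (as returned by [read_fasta()]).
#' @return The filtered data frame (possibly zero rows).
#' @export
#' @examples
#' recs <- data.frame(id = c("a", "b"), sequence = c("MKV", "MXV"))
#' filter_sequences(recs)
filter_sequences <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) return(records)
  pattern <- paste0("[", paste(EXCLUDED_LETTERS, collapse = ""), "]")
  keep <- !grepl(pattern, records$sequence)
  records[keep, , drop = FALSE]
}

#' Construct a PSSM profile object
#'
#' @param record_id Identifier string.
#' @param sequence Residue string of length L.
#' @param scores Numeric L x 20 matrix of position-specific scores, columns
#'   in the canonical order `ACDEFGHIKLMNPQRSTVWY`.
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(record_id, sequence, scores) {
  scores <- as.matrix(scores)
  L <- nchar(sequence)
  if (nrow(scores) != L) {
    stop("PSSM row count (", nrow(scores), ") does not match sequence length (",
         L, ") for record '", record_id, "'", call. = FALSE)
  }
  if (ncol(scores) != 20L) {
    stop("PSSM must have exactly 20 score columns, got ", ncol(scores), call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("PSSM scores must be finite", call. = FALSE)
  colnames(scores) <- AA_ALPHABET
  structure(list(record_id = record_id, sequence = sequence, scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$record_id, ": L = ", nchar(x$sequence),
      ", 20 score columns\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the layout written by `psiblast -out_ascii_pssm`: header lines, a
#' column-header line naming the 20 residue columns (twice, when the weighted
#' percentage block is present), then one row per residue carrying the index,
#' the residue letter and the first block of 20 log-odds scores. Columns are
#' permuted into the canonical order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param path Path to an ASCII PSSM file.
#' @return A [pssm_profile()] object.
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # Column header: a line whose tokens are >= 20 single letters.
  header_at <- NA_integer_
  file_order <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20L && all(nchar(toks) == 1L) &&
        all(toks %in% c(LETTERS, "*", "-"))) {
      header_at <- i
      file_order <- toks[seq_len(20L)]
      break
    }
  }
  if (is.na(header_at)) {
    stop("'", path, "': no PSSM column-header line found", call. = FALSE)
  }
  if (anyDuplicated(file_order) || !all(sort(file_order) == AA_ALPHABET)) {
    stop("'", path, "': column header is not a permutation of the 20 amino-acid letters",
         call. = FALSE)
  }
  residues <- character(0)
  rows <- list()
  data_lines <- if (header_at < length(lines)) {
    seq(header_at + 1L, length(lines))
  } else {
    integer(0)
  }
  for (i in data_lines) {
    line <- trimws(lines[i])
    if (line == "") break
    toks <- strsplit(line, "\\s+")[[1]]
    # data rows start "<index> <residue> <20+ numbers>"; anything else after
    # the data block is the trailer
    if (is.na(suppressWarnings(as.integer(toks[1])))) break
    if (length(toks) < 22L) {
      stop("'", path, "' line ", i, ": expected at least 20 score columns, found ",
           length(toks) - 2L, call. = FALSE)
    }
    if (nchar(toks[2]) != 1L || !(toks[2] %in% LETTERS)) {
      stop("'", path, "' line ", i, ": expected a residue letter in column 2",
           call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(vals))) {
      stop("'", path, "' line ", i, ": non-numeric score in the first 20-column block",
           call. = FALSE)
    }
    residues[[length(residues) + 1L]] <- toks[2]
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L) {
    stop("'", path, "': no residue rows found after the column header", call. = FALSE)
  }
  scores <- do.call(rbind, rows)
  colnames(scores) <- file_order
  scores <- scores[, AA_ALPHABET, drop = FALSE]
  id <- sub("\\.[^.]*$", "", basename(path))
  pssm_profile(id, paste(unlist(residues), collapse = ""), scores)
}

#' Construct a secondary-structure track object
#'
#' @param record_id Identifier string.
#' @param states Character string over `{H,E,C}` of length L.
#' @param probs Numeric L x 3 matrix of per-residue state probabilities,
#'   columns in (C, H, E) order; each row must sum to 1 within `tol`.
#' @param tol Row-sum tolerance (default 1e-3).
#' @return An object of class `ss_track`.
#' @export
ss_track <- function(record_id, states, probs, tol = 1e-3) {
  probs <- as.matrix(probs)
  L <- nchar(states)
  st <- strsplit(states, "")[[1]]
  if (!all(st %in% SS_STATES)) {
    bad <- unique(st[!(st %in% SS_STATES)])
    stop("unknown secondary-structure state letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(probs) != L) {
    stop("probability matrix has ", nrow(probs), " rows but states string has length ",
         L, call. = FALSE)
  }
  if (ncol(probs) != 3L) stop("probability matrix must have 3 columns", call. = FALSE)
  if (any(probs < 0) || any(probs > 1) || any(!is.finite(probs))) {
    stop("state probabilities must lie in [0, 1]", call. = FALSE)
  }
  bad <- which(abs(rowSums(probs) - 1) > tol)
  if (length(bad) > 0L) {
    stop("probability rows do not sum to 1 (rows ",
         paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  colnames(probs) <- SS_STATES
  structure(list(record_id = record_id, states = states, probs = probs),
            class = "ss_track")
}

#' @export
print.ss_track <- function(x, ...) {
  cat("<ss_track> ", x$record_id, ": L = ", nchar(x$states), "\n", sep = "")
  invisible(x)
}

#' Read a PSI-PRED ss2 file
#'
#' Parses the PSI-PRED VFORMAT: comment/blank lines, then one row per
#' residue with index, residue letter, state letter and the three state
#' probabilities in file order (coil, helix, strand). Probabilities are kept
#' in (C, H, E) column order.
#'
#' @param path Path to a `.ss2` file.
#' @param tol Row-sum tolerance on the probabilities (default 1e-2; predictor
#'   output is printed to three decimals).
#' @return An [ss_track()] object.
#' @export
read_ss2 <- function(path, tol = 1e-2) {
  if (!file.exists(path)) stop("ss2 file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  states <- character(0)
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    toks <- strsplit(line, "\\s+")[[1]]
    if (length(toks) != 6L) {
      stop("'", path, "' line ", i, ": expected 6 fields (index residue state pC pH pE)",
           call. = FALSE)
    }
    if (!(toks[3] %in% SS_STATES)) {
      stop("'", path, "' line ", i, ": unknown state letter '", toks[3], "'",
           call. = FALSE)
    }
    p <- suppressWarnings(as.numeric(toks[4:6]))
    if (any(is.na(p))) {
      stop("'", path, "' line ", i, ": non-numeric probability", call. = FALSE)
    }
    if (abs(sum(p) - 1) > tol) {
      stop("'", path, "' line ", i, ": probabilities sum to ", format(sum(p)),
           ", outside 1 ± ", tol, call. = FALSE)
    }
    states[[length(states) + 1L]] <- toks[3]
    rows[[length(rows) + 1L]] <- p
  }
  if (length(rows) == 0L) stop("'", path, "': no residue rows found", call. = FALSE)
  probs <- do.call(rbind, rows)
  probs <- probs / rowSums(probs)
  id <- sub("\\.[^.]*$", "", basename(path))
  ss_track(id, paste(states, collapse = ""), probs)
}

#' Construct a labeled feature dataset
#'
#' @param ids Character vector of record identifiers.
#' @param features Numeric n x d matrix.
#' @param labels Integer/numeric vector of 0/1 labels (1 = antioxidant).
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(ids, features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(ids) != nrow(features) || length(labels) != nrow(features)) {
    stop("ids, features rows and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  structure(list(ids = as.character(ids), features = features, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$features), " samples x ", ncol(x$features),
      " features (", sum(x$labels == 1L), " positive / ", sum(x$labels == 0L),
      " negative)\n", sep = "")
  invisible(x)
}

feature_column_names <- function(d) sprintf("f%03d", seq_len(d))

#' Write / read a labeled feature table as CSV
#'
#' The on-disk layout is `id,label,f001..f<d>` with full-precision numeric
#' output, so a write/read round trip reproduces the features to better than
#' 1e-9 relative error.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a [labeled_dataset()].
#' @export
write_feature_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  d <- ncol(dataset$features)
  dt <- data.table::data.table(id = dataset$ids, label = dataset$labels)
  if (nrow(dt) > 0L) {
    feat <- data.table::as.data.table(dataset$features)
    data.table::setnames(feat, feature_column_names(d))
    dt <- cbind(dt, feat)
  } else {
    for (nm in feature_column_names(d)) dt[[nm]] <- numeric(0)
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @param expected_dim Optional feature dimensionality to enforce on read.
#' @export
read_feature_table <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE)
  if (!all(c("id", "label") %in% names(dt))) {
    stop("'", path, "': feature table must start with 'id,label' columns", call. = FALSE)
  }
  feat_cols <- setdiff(names(dt), c("id", "label"))
  if (!is.null(expected_dim) && length(feat_cols) != expected_dim) {
    stop("'", path, "': expected ", expected_dim, " feature columns, found ",
         length(feat_cols), call. = FALSE)
  }
  features <- as.matrix(dt[, feat_cols, with = FALSE])
  storage.mode(features) <- "double"
  labeled_dataset(dt$id, features, dt$label)
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits the standard ASCII dialect (two header lines, the doubled 20-letter
#' column header, per-residue rows with the 20 log-odds scores and a dummy
#' percentage block, and a trailer) so the output is parseable by
#' [read_pssm()] and by other tools expecting the layout.
#'
#' @param profile A [pssm_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  scores <- profile$scores
  res <- strsplit(profile$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
             con)
  hdr <- paste0("          ",
                paste(sprintf("%4s", AA_ALPHABET), collapse = ""), " ",
                paste(sprintf("%4s", AA_ALPHABET), collapse = ""))
  writeLines(hdr, con)
  for (i in seq_len(nrow(scores))) {
    row <- paste0(sprintf("%5d %s ", i, res[i]),
                  paste(sprintf("%4d", round(scores[i, ])), collapse = ""), " ",
                  paste(sprintf("%4d", rep(0L, 20L)), collapse = ""),
                  sprintf("  %4.2f %8.2f", 0, 0))
    writeLines(row, con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Write a secondary-structure track in PSI-PRED ss2 layout
#'
#' @param track An [ss_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(track, path) {
  stopifnot(inherits(track, "ss_track"))
  st <- strsplit(track$states, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# PSF format file generated in the PSI-PRED VFORMAT dialect", ""), con)
  for (i in seq_along(st)) {
    writeLines(sprintf("%4d A %s  %6.3f %6.3f %6.3f", i, st[i],
                       track$probs[i, "C"], track$probs[i, "H"], track$probs[i, "E"]),
               con)
  }
  invisible(path)
}
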