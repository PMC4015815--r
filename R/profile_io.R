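#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that returns plain
#' uppercased residue strings and enforces the package's input contract:
#' a record body may contain ambiguity codes (handled downstream by masking),
#' identifiers must be unique, and a sequence line before the first header is
#' reported with its line number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of residue strings (possibly length 0),
#'   names are the record identifiers (first whitespace-delimited token of the
#'   header), order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(structure(character(0), names = character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA in '%s': sequence data before first header at line %d",
                 path, nonblank[1]), call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("FASTA records with empty sequences: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Construct a frequency profile
#'
#' A frequency profile holds, for each position of a protein, the frequencies
#' of the 20 standard amino acids estimated from a multiple sequence alignment
#' (in practice, the percentage block of a PSI-BLAST PSSM). Rows are
#' renormalised to sum to 1; all-zero rows (positions where the aligner
#' reported no observations) become uniform rows and are flagged.
#'
#' @param freq Numeric L x 20 matrix of non-negative frequencies. Columns must
#'   be in [aa_alphabet()] order (use `alphabet_order` to declare a different
#'   input order; columns are reordered).
#' @param id Sequence identifier.
#' @param alphabet_order Character vector giving the amino-acid order of the
#'   columns of `freq`. Default: the package alphabet.
#' @return Object of class `frequency_profile`: list with `id`, `freq`
#'   (L x 20, rows summing to 1, columns in alphabet order) and
#'   `uniform_rows` (indices of rows that were all zero on input).
#' @export
frequency_profile <- function(freq, id = "seq", alphabet_order = aa_alphabet()) {
  freq <- as.matrix(freq)
  if (ncol(freq) != 20L) stop("profile must have 20 columns", call. = FALSE)
  if (nrow(freq) < 1L) stop("profile must have at least one row", call. = FALSE)
  if (any(freq < 0)) stop("profile frequencies must be non-negative", call. = FALSE)
  perm <- match(aa_alphabet(), toupper(alphabet_order))
  if (anyNA(perm)) stop("alphabet_order must contain all 20 standard amino acids", call. = FALSE)
  freq <- freq[, perm, drop = FALSE]
  rs <- rowSums(freq)
  uniform_rows <- which(rs == 0)
  if (length(uniform_rows)) {
    freq[uniform_rows, ] <- 1 / 20
    rs[uniform_rows] <- 1
  }
  freq <- freq / rs
  dimnames(freq) <- list(NULL, aa_alphabet())
  structure(list(id = as.character(id), freq = freq,
                 uniform_rows = as.integer(uniform_rows)),
            class = "frequency_profile")
}

#' @export
length.frequency_profile <- function(x) nrow(x$freq)

#' @export
print.frequency_profile <- function(x, ...) {
  cat(sprintf("Frequency profile '%s': %d positions x 20 amino acids", x$id, nrow(x$freq)))
  if (length(x$uniform_rows))
    cat(sprintf(" (%d all-zero rows made uniform)", length(x$uniform_rows)))
  cat("\nTop-1-gram sequence: ")
  print(top_ngram_encode(x, 1))
  invisible(x)
}

# PSI-BLAST prints its matrix columns in this order; used as the fallback
# when a PSSM file carries no parsable header line.
PSIBLAST_COLUMN_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a frequency profile from a PSI-BLAST ASCII PSSM file
#'
#' Parses the classic PSI-BLAST `-Q` ASCII layout: header lines, then one row
#' per position with the position number, the query residue, 20 log-odds
#' values, 20 weighted observed percentages and trailing statistics. Only the
#' percentage block is used: it is divided by 100 and row-renormalised into a
#' [frequency_profile()]. The column order is taken from the file's header
#' line of 40 amino-acid letters when present, otherwise PSI-BLAST's standard
#' order is assumed.
#'
#' A plain whitespace-separated L x 20 matrix with a one-line header of 20
#' amino-acid letters is accepted as a secondary dialect (see
#' [read_profile_matrix()]); `read_pssm()` dispatches on the file shape.
#'
#' @param path Path to the PSSM file.
#' @param id Identifier for the profile; defaults to the file name without
#'   extension.
#' @return A [frequency_profile()].
#' @export
read_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])

  is_data <- vapply(toks, function(tk) {
    length(tk) >= 3L && grepl("^[0-9]+$", tk[1]) && grepl("^[A-Za-z]$", tk[2])
  }, logical(1))
  if (!any(is_data)) {
    # fall back to the plain-matrix fixture dialect
    return(read_profile_matrix(path, id = id))
  }

  # column order from the header: a line of 40 (or 20) single letters
  ord <- PSIBLAST_COLUMN_ORDER
  hdr <- which(vapply(toks, function(tk) {
    length(tk) %in% c(20L, 40L) && all(grepl("^[A-Za-z]$", tk))
  }, logical(1)))
  if (length(hdr)) {
    tk <- toks[[hdr[1]]]
    ord <- toupper(if (length(tk) == 40L) tk[21:40] else tk)
  }

  rows <- which(is_data)
  pct <- matrix(NA_real_, length(rows), 20L)
  for (k in seq_along(rows)) {
    tk <- toks[[rows[k]]]
    if (length(tk) < 42L) {
      stop(sprintf("malformed PSSM row at line %d of '%s': %d fields (expected >= 42)",
                   rows[k], path, length(tk)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tk[23:42]))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric percentage value at line %d of '%s'", rows[k], path),
           call. = FALSE)
    }
    pct[k, ] <- vals
  }
  frequency_profile(pct / 100, id = id, alphabet_order = ord)
}

#' Read / write the plain-matrix profile dialect
#'
#' Fixture dialect: a one-line header of 20 amino-acid letters, then one
#' whitespace-separated row of 20 frequencies per position.
#'
#' @param path File path.
#' @param id Profile identifier.
#' @return `read_profile_matrix()` returns a [frequency_profile()];
#'   `write_profile_matrix()` returns `path` invisibly.
#' @export
read_profile_matrix <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("profile matrix file needs a header and >= 1 row: ", path, call. = FALSE)
  hdr <- toupper(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 20L || !all(grepl("^[A-Z]$", hdr))) {
    stop("profile matrix header must list 20 one-letter amino-acid codes: ", path, call. = FALSE)
  }
  vals <- lapply(lines[-1], function(l) suppressWarnings(as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  n <- vapply(vals, length, integer(1))
  if (any(n != 20L)) {
    stop(sprintf("profile matrix row %d has %d fields (expected 20)",
                 which(n != 20L)[1], n[n != 20L][1]), call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (anyNA(m)) stop("non-numeric value in profile matrix: ", path, call. = FALSE)
  frequency_profile(m, id = id, alphabet_order = hdr)
}

#' @rdname read_profile_matrix
#' @param profile A [frequency_profile()].
#' @export
write_profile_matrix <- function(profile, path) {
  stopifnot(inherits(profile, "frequency_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(aa_alphabet(), collapse = " "), con)
  apply(profile$freq, 1, function(r) {
    writeLines(paste(formatC(r, format = "g", digits = 12), collapse = " "), con)
  })
  invisible(path)
}

#' Write a frequency profile in the PSI-BLAST ASCII PSSM layout
#'
#' Emits the row layout [read_pssm()] consumes (position, residue, 20 zero
#' log-odds placeholders, 20 percentages, two trailing statistics), with
#' percentages at full precision so a read/write round trip reproduces the
#' matrix to numerical accuracy.
#'
#' @param profile A [frequency_profile()].
#' @param path Output file path.
#' @param residues Optional residue string for the second column; defaults to
#'   the per-row Top-1-gram.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path, residues = NULL) {
  stopifnot(inherits(profile, "frequency_profile"))
  L <- nrow(profile$freq)
  if (is.null(residues)) {
    residues <- aa_alphabet()[top_ngram_encode(profile, 1)$symbols]
  } else {
    residues <- strsplit(toupper(residues), "")[[1]]
    stopifnot(length(residues) == L)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines("Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts", con)
  writeLines(paste(" ", paste(c(aa_alphabet(), aa_alphabet()), collapse = "  ")), con)
  pct <- profile$freq * 100
  for (i in seq_len(L)) {
    writeLines(paste(i, residues[i],
                     paste(rep("0", 20), collapse = " "),
                     paste(formatC(pct[i, ], format = "g", digits = 12), collapse = " "),
                     "0.00 0.00"), con)
  }
  invisible(path)
}

#' Encode a frequency profile as Top-n-grams
#'
#' For every profile position, the `n` amino acids with the highest
#' frequencies, ordered by decreasing frequency (the order carries meaning:
#' earlier symbols dominated the alignment column). Ties are broken towards
#' the symbol earliest in [aa_alphabet()], a fixed deterministic rule. For
#' `n = 1` — the encoding the distance-pair features consume — the result is a
#' [symbol_sequence()] of Top-1-grams.
#'
#' @param profile A [frequency_profile()].
#' @param n Number of top amino acids per position, in `[1, 20]`.
#' @return For `n = 1`, a [symbol_sequence()]; otherwise an L x n integer
#'   matrix of alphabet indices, one row per position, columns in decreasing
#'   frequency order.
#' @export
#' @examples
#' p <- frequency_profile(diag(20)[c(12, 14, 14, 12), ])  # K, F, F, K
#' top_ngram_encode(p, 1)  # "KFFK"
top_ngram_encode <- function(profile, n = 1L) {
  stopifnot(inherits(profile, "frequency_profile"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > 20L) stop("n must be in [1, 20]", call. = FALSE)
  # order() is stable, so ties fall to the lower column index = alphabet order
  ord <- t(apply(profile$freq, 1, function(r) order(r, decreasing = TRUE)[seq_len(n)]))
  if (n == 1L) {
    return(symbol_sequence(as.integer(ord), id = profile$id))
  }
  matrix(as.integer(ord), nrow = nrow(profile$freq), ncol = n,
         dimnames = list(NULL, paste0("rank", seq_len(n))))
}
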