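#' The Top-1-gram / residue alphabet
#'
#' The fixed, ordered 20-symbol amino-acid alphabet used throughout the
#' package: \code{A, R, D, C, Q, E, H, I, G, N, L, K, M, F, P, S, T, W, Y, V}.
#' Feature-vector layout, tie-breaking and all heatmap exports use this order;
#' symbol 1 is \code{A} and symbol 20 is \code{V}.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()[1]   # "A"
#' aa_alphabet()[20]  # "V"
aa_alphabet <- function() {
  c("A", "R", "D", "C", "Q", "E", "H", "I", "G", "N",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# residues that are legal in input but carry no standard symbol
AMBIGUITY_CODES <- c("B", "Z", "X", "U", "O")

#' Convert a symbol (letter or index) to a validated alphabet index
#' @noRd
as_symbol_index <- function(x, arg = deparse(substitute(x))) {
  if (is.character(x)) {
    idx <- match(toupper(x), aa_alphabet())
    if (anyNA(idx)) {
      stop(sprintf("'%s' contains symbols outside the 20-letter alphabet: %s",
                   arg, paste(x[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(x)
  if (anyNA(idx) || any(idx < 1L) || any(idx > 20L)) {
    stop(sprintf("'%s' must be alphabet indices in [1, 20]", arg), call. = FALSE)
  }
  idx
}

#' Construct a symbol sequence
#'
#' A symbol sequence is the common input to feature construction: a vector of
#' indices into [aa_alphabet()] with a per-position validity mask. Positions
#' holding ambiguity codes (B, Z, X, U, O) or other non-standard characters
#' are invalid: they contribute to no unigram or pair count.
#'
#' @param symbols Integer vector of alphabet indices (1--20), or a character
#'   vector/string of one-letter symbols. `NA` marks an invalid position.
#' @param id Sequence identifier.
#' @param valid Optional logical mask, same length as `symbols`.
#' @return An object of class `symbol_sequence` with fields `id`, `symbols`
#'   (integer, `NA` at invalid positions) and `valid` (logical).
#' @export
#' @examples
#' symbol_sequence("KFFK")
symbol_sequence <- function(symbols, id = "seq", valid = NULL) {
  if (is.character(symbols)) {
    if (length(symbols) == 1L) symbols <- strsplit(symbols, "")[[1]]
    idx <- match(toupper(symbols), aa_alphabet())
  } else {
    idx <- as.integer(symbols)
    if (any(idx < 1L | idx > 20L, na.rm = TRUE)) {
      stop("symbol indices must be in [1, 20] or NA", call. = FALSE)
    }
  }
  if (length(idx) < 1L) stop("a symbol sequence must have length >= 1", call. = FALSE)
  if (is.null(valid)) valid <- !is.na(idx)
  stopifnot(length(valid) == length(idx))
  idx[!valid] <- NA_integer_
  structure(list(id = as.character(id), symbols = idx, valid = valid),
            class = "symbol_sequence")
}

#' @export
length.symbol_sequence <- function(x) length(x$symbols)

#' @export
print.symbol_sequence <- function(x, ...) {
  chars <- ifelse(x$valid, aa_alphabet()[x$symbols], ".")
  cat(sprintf("Symbol sequence '%s' (%d positions, %d valid)\n",
              x$id, length(x), sum(x$valid)))
  cat(paste(chars, collapse = ""), "\n")
  invisible(x)
}

#' Map a protein sequence to alphabet indices
#'
#' Each standard residue is mapped to its index in [aa_alphabet()]; positions
#' holding ambiguity codes (B, Z, X, U, O) or any other non-standard character
#' are marked invalid rather than mapped to an extra symbol, so the feature
#' dimension stays tied to the 20-letter alphabet.
#'
#' @param residues A single string of one-letter residue codes, or a named
#'   length-one character vector as returned by [read_fasta()].
#' @param id Identifier; defaults to the name of `residues` if present.
#' @return A [symbol_sequence()]. The number of masked positions is available
#'   as `sum(!x$valid)`.
#' @export
#' @examples
#' s <- residues_to_symbols("AGLP")
#' aa_alphabet()[s$symbols]
#' residues_to_symbols("AXA")$valid  # TRUE FALSE TRUE
residues_to_symbols <- function(residues, id = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (is.null(id)) id <- if (!is.null(names(residues))) names(residues) else "seq"
  chars <- strsplit(toupper(residues), "")[[1]]
  if (length(chars) < 1L) stop("protein sequence must have length >= 1", call. = FALSE)
  idx <- match(chars, aa_alphabet())
  symbol_sequence(idx, id = id)
}

#' Coerce strings / symbol sequences to symbol_sequence
#' @noRd
as_symbol_sequence <- function(s, id = "seq") {
  if (inherits(s, "symbol_sequence")) return(s)
  if (is.character(s) && length(s) == 1L) return(residues_to_symbols(s, id = id))
  stop("expected a symbol_sequence or a single residue string", call. = FALSE)
}
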