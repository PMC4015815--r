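#' Dimension of a distance feature vector
#'
#' The feature vector over the 20-symbol alphabet has one block of 20 unigram
#' counts (distance 0) plus one 20 x 20 block of ordered-pair counts for each
#' distance `1 <= d <= d_max`, giving `20 + 400 * d_max` components.
#'
#' @param d_max Distance threshold (non-negative integer).
#' @return Integer vector length.
#' @export
#' @examples
#' feature_dimension(150)  # 60020
feature_dimension <- function(d_max) {
  d_max <- as.integer(d_max)
  if (is.na(d_max) || d_max < 0L) stop("d_max must be a non-negative integer", call. = FALSE)
  20L + 400L * d_max
}

#' Position of a feature in the distance feature vector
#'
#' The layout is frozen for file-format stability: the 20 unigram counts come
#' first (in [aa_alphabet()] order), followed by the flattened 20 x 20 pair
#' blocks in increasing distance order. Indices are 1-based: unigram `a` maps
#' to `a`, and pair `(a, b)` at distance `d` maps to
#' `20 + 400 * (d - 1) + 20 * (a - 1) + b`.
#'
#' @param kind `"unigram"` or `"pair"`.
#' @param first,second Alphabet symbols, as one-letter codes or indices in
#'   `[1, 20]`. `second` is required for pairs; `first` occurs before `second`
#'   in the sequence (ordered pairs: `(a, b)` and `(b, a)` are distinct).
#' @param d Distance: 0 for unigrams, `>= 1` for pairs.
#' @param d_max If supplied, `d` is additionally checked against it.
#' @return 1-based integer index.
#' @export
#' @examples
#' feature_index("unigram", "A")                 # 1
#' feature_index("pair", "A", "A", d = 1)        # 21
#' feature_index("pair", "V", "V", d = 2)        # 820
feature_index <- function(kind = c("unigram", "pair"), first, second = NULL,
                          d = if (kind == "unigram") 0L else NULL,
                          d_max = NULL) {
  kind <- match.arg(kind)
  a <- as_symbol_index(first, "first")
  if (kind == "unigram") {
    if (!all(d == 0L)) stop("unigram features live at distance 0", call. = FALSE)
    return(a)
  }
  if (is.null(second) || is.null(d)) stop("pair features need 'second' and 'd'", call. = FALSE)
  b <- as_symbol_index(second, "second")
  d <- as.integer(d)
  if (anyNA(d) || any(d < 1L)) stop("pair distance must be >= 1", call. = FALSE)
  if (!is.null(d_max) && any(d > d_max)) {
    stop("distance exceeds d_max = ", d_max, call. = FALSE)
  }
  20L + 400L * (d - 1L) + 20L * (a - 1L) + b
}

#' Count ordered symbol pairs at one distance
#'
#' Entry `(a, b)` counts position pairs `(p, p + d)` where both positions are
#' valid, the symbol at `p` is `a` and the symbol at `p + d` is `b`. Pairs
#' spanning a masked (invalid) position are dropped, not bridged.
#'
#' @param s A [symbol_sequence()] or residue string.
#' @param d Distance (positional offset), `>= 1`; adjacent symbols have `d = 1`.
#' @return 20 x 20 integer matrix with [aa_alphabet()] dimnames; rows index
#'   the first (earlier) symbol.
#' @export
#' @examples
#' count_distance_block("KFFK", 1)["K", "F"]  # 1
count_distance_block <- function(s, d) {
  s <- as_symbol_sequence(s)
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("d must be >= 1", call. = FALSE)
  L <- length(s)
  m <- matrix(0L, 20L, 20L, dimnames = list(aa_alphabet(), aa_alphabet()))
  if (d < L) {
    i <- seq_len(L - d)
    a <- s$symbols[i]
    b <- s$symbols[i + d]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      counts <- tabulate(20L * (a[ok] - 1L) + b[ok], nbins = 400L)
      m <- matrix(counts, 20L, 20L, byrow = TRUE,
                  dimnames = list(aa_alphabet(), aa_alphabet()))
    }
  }
  m
}

#' Build the distance feature vector of a symbol sequence
#'
#' Concatenates the unigram composition (distance-0 block) with the flattened
#' ordered-pair count blocks for every distance from 1 to `d_max`, in the
#' layout of [feature_index()]. Runs in O(L * d_max): each distance is one
#' vectorised pass over the sequence.
#'
#' @param s A [symbol_sequence()] or residue string.
#' @param d_max Distance threshold (non-negative integer; 0 keeps only the
#'   composition block).
#' @return Integer count vector of length `20 + 400 * d_max`, with attributes
#'   `d_max` and `id`.
#' @export
#' @examples
#' v <- build_feature_vector("KFFK", d_max = 2)
#' length(v)      # 820
#' sum(v != 0)    # 7
build_feature_vector <- function(s, d_max) {
  s <- as_symbol_sequence(s)
  d_max <- as.integer(d_max)
  if (is.na(d_max) || d_max < 0L) stop("d_max must be a non-negative integer", call. = FALSE)
  v <- integer(feature_dimension(d_max))
  v[1:20] <- tabulate(s$symbols[!is.na(s$symbols)], nbins = 20L)
  L <- length(s)
  for (d in seq_len(d_max)) {
    if (d >= L) break
    i <- seq_len(L - d)
    a <- s$symbols[i]
    b <- s$symbols[i + d]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      v[20L + 400L * (d - 1L) + seq_len(400L)] <-
        tabulate(20L * (a[ok] - 1L) + b[ok], nbins = 400L)
    }
  }
  structure(v, d_max = d_max, id = s$id)
}

#' Distance-based residue features (the SVM-DR representation)
#'
#' The native protein sequence is converted directly into the distance feature
#' vector, without profile information: composition
#' `build_feature_vector(residues_to_symbols(seq), d_max)`.
#'
#' @param seq Residue string (possibly named) or [symbol_sequence()].
#' @param d_max Distance threshold; default 150, the method's operating point.
#' @param id Optional identifier.
#' @return Integer count vector as in [build_feature_vector()].
#' @export
dr_features <- function(seq, d_max = 150L, id = NULL) {
  s <- if (inherits(seq, "symbol_sequence")) seq else
    residues_to_symbols(seq, id = id)
  build_feature_vector(s, d_max)
}

#' Distance-based Top-1-gram features (the SVM-DT representation)
#'
#' The profile is first encoded as its Top-1-gram sequence (the most frequent
#' amino acid of each column), then converted into the distance feature
#' vector: composition `build_feature_vector(top_ngram_encode(profile, 1),
#' d_max)`.
#'
#' @param profile A [frequency_profile()].
#' @param d_max Distance threshold; default 150.
#' @return Integer count vector as in [build_feature_vector()].
#' @export
dt_features <- function(profile, d_max = 150L) {
  stopifnot(inherits(profile, "frequency_profile"))
  build_feature_vector(top_ngram_encode(profile, 1L), d_max)
}

#' Write / read sparse feature files (SVM-light format)
#'
#' One line per vector: the label followed by `index:value` pairs with
#' 1-based, strictly ascending indices (the layout of [feature_index()]).
#'
#' @param vectors List of feature vectors from [build_feature_vector()] (or a
#'   numeric matrix with one row per vector), all with the same `d_max`.
#' @param labels Numeric vector of +1 / -1 labels, one per vector.
#' @param path Output file path.
#' @param d_max Required when `vectors` is a plain matrix.
#' @return `write_sparse_features()` returns `path` invisibly;
#'   `read_sparse_features()` returns a list with `x` (dense numeric matrix),
#'   `labels`, and `d_max`.
#' @export
write_sparse_features <- function(vectors, labels, path, d_max = NULL) {
  if (is.matrix(vectors)) {
    stopifnot(!is.null(d_max))
    vectors <- lapply(seq_len(nrow(vectors)), function(i) {
      structure(vectors[i, ], d_max = as.integer(d_max))
    })
  }
  if (length(vectors) != length(labels)) {
    stop("need one label per feature vector", call. = FALSE)
  }
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1", call. = FALSE)
  dms <- vapply(vectors, function(v) as.integer(attr(v, "d_max")), integer(1))
  if (length(unique(dms)) > 1L) {
    stop("inconsistent d_max across feature vectors: ",
         paste(unique(dms), collapse = ", "), call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(vectors)) {
    writeLines(sprintf("# d_max=%d dim=%d", dms[1], feature_dimension(dms[1])), con)
  }
  for (i in seq_along(vectors)) {
    v <- as.numeric(vectors[[i]])
    nz <- which(v != 0)
    writeLines(paste(c(sprintf("%+d", as.integer(labels[i])),
                       sprintf("%d:%.10g", nz, v[nz])), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_sparse_features
#' @export
read_sparse_features <- function(path, d_max = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  if (is.null(d_max)) {
    m <- regmatches(lines[hdr], regexpr("d_max=[0-9]+", lines[hdr]))
    if (length(m)) d_max <- as.integer(sub("d_max=", "", m[1]))
  }
  lines <- lines[!hdr & nzchar(trimws(lines))]
  if (is.null(d_max)) stop("d_max not given and not found in file header", call. = FALSE)
  dim <- feature_dimension(d_max)
  x <- matrix(0, length(lines), dim)
  labels <- numeric(length(lines))
  for (i in seq_along(lines)) {
    tk <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    labels[i] <- as.numeric(tk[1])
    if (length(tk) > 1L) {
      kv <- strsplit(tk[-1], ":", fixed = TRUE)
      idx <- as.integer(vapply(kv, `[`, character(1), 1L))
      val <- as.numeric(vapply(kv, `[`, character(1), 2L))
      if (anyNA(idx) || anyNA(val) || any(idx < 1L) || any(idx > dim)) {
        stop("malformed sparse feature line ", i, " in ", path, call. = FALSE)
      }
      x[i, idx] <- val
    }
  }
  list(x = x, labels = labels, d_max = as.integer(d_max))
}
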