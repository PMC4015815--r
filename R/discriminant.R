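#' Discriminant weight vector of a linear family classifier
#'
#' Recovers the explicit weight vector `w = M alpha` from the kernel
#' expansion, where the columns of `M` are the training feature vectors as
#' scored (unit-normalised when the model normalises) and `alpha` the
#' label-signed dual coefficients. For the linear kernel,
#' `score(model, v) == sum(w * normalize(v)) + bias` exactly, and the
#' magnitude of each component measures the discriminative power of the
#' corresponding feature.
#'
#' @param model A `trained_model` with a linear kernel.
#' @param M Optional feature matrix (one training vector per row, ordered as
#'   `model$alpha`); defaults to the matrix stored in the model. Supplying a
#'   matrix with mismatched dimensions is an error.
#' @return Object of class `discriminant_weights`: numeric vector `w` of
#'   length `20 + 400 * d_max` with attributes `d_max`, `bias`, `model_ids`.
#' @export
discriminant_weights <- function(model, M = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (model$config$kernel != "linear") {
    stop("discriminant weights require a linear kernel", call. = FALSE)
  }
  if (is.null(M)) {
    M <- model$X
  } else {
    M <- as.matrix(M)
    if (nrow(M) != length(model$alpha) || ncol(M) != ncol(model$X)) {
      stop(sprintf("M must be %d x %d (training samples x features), got %d x %d",
                   length(model$alpha), ncol(model$X), nrow(M), ncol(M)),
           call. = FALSE)
    }
  }
  w <- as.numeric(crossprod(M, model$alpha))
  structure(w, class = "discriminant_weights",
            d_max = model$d_max, bias = model$bias, model_ids = model$ids)
}

#' @export
print.discriminant_weights <- function(x, ...) {
  cat(sprintf("Discriminant weight vector: %d features (d_max = %s), |w| = %.4g\n",
              length(x), format(attr(x, "d_max")), sqrt(sum(x^2))))
  invisible(x)
}

infer_d_max <- function(w) {
  d_max <- attr(w, "d_max")
  if (is.null(d_max) || is.na(d_max)) d_max <- (length(w) - 20L) %/% 400L
  if (feature_dimension(d_max) != length(w)) {
    stop("weight vector length is not 20 + 400 * d_max", call. = FALSE)
  }
  as.integer(d_max)
}

#' Per-pair importance of the discriminant weights
#'
#' Collapses the weight vector over distances: the importance of ordered pair
#' `(a, b)` is the L2-norm of its weights across all distances `1..d_max`,
#' `sqrt(sum_d w[(a, b, d)]^2)`; unigram importances `|w[a]|` are reported
#' separately (the distance-0 block is not a pair).
#'
#' @param w A `discriminant_weights` vector (or plain numeric vector of valid
#'   length).
#' @return Object of class `pair_importance`: list with `pairs` (20 x 20
#'   non-negative matrix; rows = first symbol, columns = second symbol, in
#'   [aa_alphabet()] order) and `unigrams` (named length-20 vector).
#' @export
pair_l2_norms <- function(w) {
  d_max <- infer_d_max(w)
  w <- as.numeric(w)
  pairs <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  if (d_max > 0) {
    blocks <- matrix(w[-(1:20)]^2, nrow = 400L)  # one column per distance
    pairs <- matrix(sqrt(rowSums(blocks)), 20, 20, byrow = TRUE,
                    dimnames = list(aa_alphabet(), aa_alphabet()))
  }
  structure(list(pairs = pairs,
                 unigrams = stats::setNames(abs(w[1:20]), aa_alphabet()),
                 d_max = d_max),
            class = "pair_importance")
}

#' @export
print.pair_importance <- function(x, ...) {
  top <- order(x$pairs, decreasing = TRUE)[1:5]
  a <- aa_alphabet()[(top - 1) %% 20 + 1]
  b <- aa_alphabet()[(top - 1) %/% 20 + 1]
  cat(sprintf("Pair importance over distances 1..%d\n", x$d_max))
  cat("Top ordered pairs: ",
      paste(sprintf("(%s,%s)=%.3g", a, b, x$pairs[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Signed per-distance weight profile of one ordered pair
#'
#' Extracts `w[(a, b, d)]` for `d = 1..d_max`, the signed discriminative
#' weight of the pair at each distance — the ladder plots that show short
#' distances dominating discrimination.
#'
#' @param w A `discriminant_weights` vector.
#' @param first,second Pair symbols (letters or indices).
#' @return Numeric vector of length `d_max`; entry `d` is the weight of the
#'   pair at distance `d`.
#' @export
pair_distance_profile <- function(w, first, second) {
  d_max <- infer_d_max(w)
  if (d_max == 0L) return(numeric(0))
  a <- as_symbol_index(first, "first")
  b <- as_symbol_index(second, "second")
  stopifnot(length(a) == 1L, length(b) == 1L)
  as.numeric(w)[feature_index("pair", a, b, d = seq_len(d_max))]
}

#' Export the 20 x 20 pair-importance matrix as TSV
#'
#' Rows and columns follow [aa_alphabet()] order (row = first symbol of the
#' ordered pair, column = second).
#'
#' @param imp A `pair_importance` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_importance_tsv <- function(imp, path) {
  stopifnot(inherits(imp, "pair_importance"))
  utils::write.table(imp$pairs, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
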