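# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration of a synthetic two-class family
#'
#' Defines a planted-signal benchmark family: positive sequences are random
#' backgrounds carrying `insertions` copies of an ordered symbol pair at a
#' fixed positional offset, negatives are pure background with the same
#' residue composition — so discrimination must come from pair-distance
#' structure, not composition. Setting `planted_pair = NULL` yields a null
#' family (positives and negatives identically distributed).
#'
#' @param n_pos_train,n_neg_train,n_pos_test,n_neg_test Split sizes.
#' @param length_range Sequence length range (inclusive), drawn uniformly.
#' @param planted_pair Length-2 character (or index) vector `(a, b)`, or
#'   `NULL` for a null family. Default `c("G", "G")`.
#' @param planted_distance Positional offset of the planted pair (`>= 1`);
#'   must be smaller than the minimum sequence length.
#' @param insertions Planted pair occurrences per positive sequence.
#' @param background Length-20 residue probability vector in [aa_alphabet()]
#'   order, summing to 1. Default uniform.
#' @param profile_concentration Mass placed on the native residue in synthetic
#'   profiles, in `(0, 1]`; above 0.5 the Top-1-gram equals the native
#'   residue at every position.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return List of class `synthetic_family_config`.
#' @export
synthetic_family_config <- function(n_pos_train = 30L, n_neg_train = 30L,
                                    n_pos_test = 20L, n_neg_test = 20L,
                                    length_range = c(80L, 150L),
                                    planted_pair = c("G", "G"),
                                    planted_distance = 5L,
                                    insertions = 3L,
                                    background = rep(1 / 20, 20),
                                    profile_concentration = 0.8,
                                    seed = 1L) {
  stopifnot(n_pos_train >= 1, n_neg_train >= 1, n_pos_test >= 1, n_neg_test >= 1,
            length(length_range) == 2L, length_range[1] >= 2,
            length_range[1] <= length_range[2],
            length(background) == 20L, all(background >= 0),
            abs(sum(background) - 1) < 1e-8,
            profile_concentration > 0, profile_concentration <= 1)
  if (!is.null(planted_pair)) {
    planted_pair <- as_symbol_index(planted_pair, "planted_pair")
    stopifnot(length(planted_pair) == 2L)
    planted_distance <- as.integer(planted_distance)
    if (planted_distance < 1L || planted_distance >= length_range[1]) {
      stop("planted_distance must be in [1, min sequence length)", call. = FALSE)
    }
    stopifnot(insertions >= 1)
  }
  structure(list(n_pos_train = as.integer(n_pos_train),
                 n_neg_train = as.integer(n_neg_train),
                 n_pos_test = as.integer(n_pos_test),
                 n_neg_test = as.integer(n_neg_test),
                 length_range = as.integer(length_range),
                 planted_pair = planted_pair,
                 planted_distance = as.integer(planted_distance),
                 insertions = as.integer(insertions),
                 background = background,
                 profile_concentration = profile_concentration,
                 seed = as.integer(seed)),
            class = "synthetic_family_config")
}

#' Generate a random background sequence
#'
#' Residues are drawn i.i.d. from `background`.
#'
#' @param length Sequence length.
#' @param background Length-20 probability vector in [aa_alphabet()] order.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return A residue string.
#' @export
generate_null_sequence <- function(length, background = rep(1 / 20, 20), seed = NULL) {
  stopifnot(length >= 1, base::length(background) == 20L)
  draw <- function() paste(sample(aa_alphabet(), length, replace = TRUE,
                                  prob = background), collapse = "")
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a sequence with a planted symbol pair
#'
#' Starts from a background sequence and overwrites `insertions`
#' non-overlapping position pairs `(p, p + distance)` with the planted
#' symbols, anchor positions drawn uniformly.
#'
#' @param length Sequence length.
#' @param pair Length-2 symbol pair `(a, b)` (letters or indices).
#' @param distance Positional offset of the pair, `>= 1`.
#' @param insertions Number of planted occurrences.
#' @param background Length-20 probability vector.
#' @param seed Optional seed.
#' @return A residue string in which `count_distance_block(seq, distance)` at
#'   the planted pair is at least `insertions`.
#' @export
generate_planted_sequence <- function(length, pair, distance, insertions = 3L,
                                      background = rep(1 / 20, 20), seed = NULL) {
  pair <- as_symbol_index(pair, "pair")
  stopifnot(base::length(pair) == 2L, distance >= 1, insertions >= 1)
  if (length < distance + 1L) {
    stop("sequence too short to host the planted pair", call. = FALSE)
  }
  if (2L * insertions > length) {
    stop("sequence too short to host ", insertions, " non-overlapping insertions",
         call. = FALSE)
  }
  draw <- function() {
    chars <- sample(aa_alphabet(), length, replace = TRUE, prob = background)
    used <- logical(length)
    placed <- 0L
    attempts <- 0L
    while (placed < insertions) {
      attempts <- attempts + 1L
      if (attempts > 1000L * insertions) {
        stop("could not place non-overlapping insertions; sequence too short",
             call. = FALSE)
      }
      p <- sample.int(length - distance, 1L)
      if (used[p] || used[p + distance]) next
      chars[p] <- aa_alphabet()[pair[1]]
      chars[p + distance] <- aa_alphabet()[pair[2]]
      used[c(p, p + distance)] <- TRUE
      placed <- placed + 1L
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Synthetic frequency profile for a sequence
#'
#' Emulates a PSI-BLAST profile: each column puts mass `concentration` on the
#' native residue and spreads the remainder over the other 19 amino acids in
#' random proportions. With `concentration > 0.5` the column maximum — hence
#' the Top-1-gram — is the native residue at every position, so
#' `concentration = 1` makes Top-1-gram and residue features identical.
#'
#' @param seq Residue string (standard residues only).
#' @param concentration Mass on the native residue, in `(0, 1]`.
#' @param id Profile id; defaults to the sequence name.
#' @param seed Optional seed.
#' @return A [frequency_profile()].
#' @export
synthetic_profile <- function(seq, concentration = 0.8, id = NULL, seed = NULL) {
  stopifnot(concentration > 0, concentration <= 1)
  s <- residues_to_symbols(seq, id = id)
  if (!all(s$valid)) stop("synthetic profiles require fully standard residues", call. = FALSE)
  draw <- function() {
    L <- length(s)
    freq <- matrix(0, L, 20)
    for (i in seq_len(L)) {
      rest <- stats::runif(19)
      rest <- rest / sum(rest) * (1 - concentration)
      freq[i, -s$symbols[i]] <- rest
      freq[i, s$symbols[i]] <- concentration
    }
    frequency_profile(freq, id = s$id)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a complete synthetic family benchmark
#'
#' Produces the four train/test id lists, the sequences (planted positives,
#' null negatives sharing the same background) and their synthetic profiles,
#' all reproducible from `cfg$seed`.
#'
#' @param cfg A [synthetic_family_config()].
#' @param family_id Family identifier used to prefix sequence ids.
#' @param profiles Generate synthetic profiles too (set `FALSE` to skip when
#'   only residue features are needed).
#' @return List with `split` ([family_split()]), `sequences` (named character
#'   vector) and `profiles` (named list of [frequency_profile()], or `NULL`).
#' @export
generate_family <- function(cfg, family_id = "fam1", profiles = TRUE) {
  stopifnot(inherits(cfg, "synthetic_family_config"))
  with_seed(cfg$seed, {
    n <- c(pos_train = cfg$n_pos_train, pos_test = cfg$n_pos_test,
           neg_train = cfg$n_neg_train, neg_test = cfg$n_neg_test)
    roles <- rep(names(n), n)
    positive <- grepl("^pos", roles)
    ids <- sprintf("%s_%s_%03d", family_id, roles,
                   unlist(lapply(n, seq_len), use.names = FALSE))
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                   length(ids), replace = TRUE)
    seqs <- vapply(seq_along(ids), function(i) {
      if (positive[i] && !is.null(cfg$planted_pair)) {
        generate_planted_sequence(lens[i], cfg$planted_pair,
                                  cfg$planted_distance, cfg$insertions,
                                  cfg$background)
      } else {
        generate_null_sequence(lens[i], cfg$background)
      }
    }, character(1))
    names(seqs) <- ids
    profs <- NULL
    if (profiles) {
      profs <- lapply(ids, function(id)
        synthetic_profile(seqs[[id]], cfg$profile_concentration, id = id))
      names(profs) <- ids
    }
    list(split = family_split(family_id,
                              positive_train = ids[roles == "pos_train"],
                              positive_test = ids[roles == "pos_test"],
                              negative_train = ids[roles == "neg_train"],
                              negative_test = ids[roles == "neg_test"]),
         sequences = seqs,
         profiles = profs)
  })
}

#' Write a synthetic family to disk
#'
#' Emits a FASTA file, one plain-matrix profile file per sequence (see
#' [write_profile_matrix()]) and a split file, for use with the command-line
#' pipeline.
#'
#' @param fam Result of [generate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(fam$split$family_id, ".fasta"))
  con <- file(fasta, "w")
  for (id in names(fam$sequences)) {
    writeLines(c(paste0(">", id), fam$sequences[[id]]), con)
  }
  close(con)
  if (!is.null(fam$profiles)) {
    pdir <- file.path(dir, "profiles")
    dir.create(pdir, showWarnings = FALSE)
    for (id in names(fam$profiles)) {
      write_profile_matrix(fam$profiles[[id]], file.path(pdir, paste0(id, ".mat")))
    }
  }
  write_family_split(fam$split, file.path(dir, paste0(fam$split$family_id, ".split")))
  invisible(dir)
}
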