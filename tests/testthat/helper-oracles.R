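# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's fast code paths: the feature oracle enumerates all
# ordered position pairs, and the ROC oracles build the curve by threshold
# sweeping and clip it geometrically.

# O(L^2) double loop over all ordered position pairs, offsets <= d_max
naive_feature_vector <- function(s, d_max) {
  if (!inherits(s, "symbol_sequence")) s <- distsvm::symbol_sequence(s)
  v <- numeric(20 + 400 * d_max)
  sym <- s$symbols
  L <- length(sym)
  for (p in seq_len(L)) {
    if (!is.na(sym[p])) v[sym[p]] <- v[sym[p]] + 1
  }
  if (d_max > 0 && L >= 2) {
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        d <- j - i
        if (d > d_max) break
        a <- sym[i]; b <- sym[j]
        if (is.na(a) || is.na(b)) next
        k <- 20 + 400 * (d - 1) + 20 * (a - 1) + b
        v[k] <- v[k] + 1
      }
    }
  }
  v
}

# full-curve trapezoid AUC by threshold enumeration
brute_roc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- c(0, vapply(th, function(t) sum(scores >= t & labels == 1), numeric(1)))
  fp <- c(0, vapply(th, function(t) sum(scores >= t & labels == -1), numeric(1)))
  sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)) / 2) /
    (max(fp) * max(tp))
}

# truncated AUC: clip the curve at fp = cap, linearly interpolating the
# crossing segment, then normalize by n_pos * min(cap, n_neg)
brute_roc50 <- function(scores, labels, cap = 50) {
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- c(0, vapply(th, function(t) sum(scores >= t & labels == 1), numeric(1)))
  fp <- c(0, vapply(th, function(t) sum(scores >= t & labels == -1), numeric(1)))
  n_pos <- max(tp); n_neg <- max(fp)
  cap <- min(cap, n_neg)
  area <- 0
  for (k in seq_len(length(th))) {
    f1 <- fp[k]; f2 <- fp[k + 1]; t1 <- tp[k]; t2 <- tp[k + 1]
    if (f2 <= cap) {
      area <- area + (f2 - f1) * (t1 + t2) / 2
    } else {
      frac <- (cap - f1) / (f2 - f1)
      tc <- t1 + frac * (t2 - t1)
      area <- area + (cap - f1) * (t1 + tc) / 2
      break
    }
  }
  area / (n_pos * cap)
}

# random symbol sequence, optionally with masked positions
random_symbol_sequence <- function(L, p_invalid = 0, id = "rnd") {
  sym <- sample.int(20L, L, replace = TRUE)
  if (p_invalid > 0) {
    sym[stats::runif(L) < p_invalid] <- NA_integer_
    if (all(is.na(sym))) sym[1] <- 1L
  }
  distsvm::symbol_sequence(sym, id = id)
}

# PSI-BLAST ASCII PSSM text with integer percentages, standard column order
# (A R N D C Q E G H I L K M F P S T W Y V), one row per residue
make_pssm_text <- function(residues, pct = NULL) {
  psi_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  chars <- strsplit(residues, "")[[1]]
  if (is.null(pct)) {
    pct <- t(vapply(chars, function(r) 100 * (psi_order == r), numeric(20)))
  }
  rows <- vapply(seq_along(chars), function(i) {
    paste(i, chars[i],
          paste(sample(-5:5, 20, replace = TRUE), collapse = " "),
          paste(round(pct[i, ]), collapse = " "),
          "0.36 0.07")
  }, character(1))
  c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste(" ", paste(c(psi_order, psi_order), collapse = "  ")),
    rows)
}

# profile whose row maxima spell out `top` (in package alphabet order)
fixture_profile <- function(top, id = "fix") {
  idx <- match(strsplit(top, "")[[1]], distsvm::aa_alphabet())
  m <- matrix(0.01, length(idx), 20)
  for (i in seq_along(idx)) m[i, idx[i]] <- 1
  distsvm::frequency_profile(m, id = id)
}

# labelled training data from a generated family
family_matrices <- function(fam, mode, d_max) {
  tr <- c(fam$split$positive_train, fam$split$negative_train)
  te <- c(fam$split$positive_test, fam$split$negative_test)
  feat <- function(ids) {
    t(vapply(ids, function(id) {
      if (mode == "dr") as.numeric(distsvm::dr_features(fam$sequences[[id]], d_max))
      else as.numeric(distsvm::dt_features(fam$profiles[[id]], d_max))
    }, numeric(distsvm::feature_dimension(d_max))))
  }
  list(x_train = feat(tr), y_train = ifelse(grepl("pos", tr), 1, -1),
       x_test = feat(te), y_test = ifelse(grepl("pos", te), 1, -1),
       ids_train = tr, ids_test = te)
}
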