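#' ROC score of discriminative scores
#'
#' The normalised area under the true-positive vs false-positive curve,
#' computed as the Mann--Whitney statistic
#' `P(score_pos > score_neg) + 0.5 * P(tie)` via midranks. Equivalent to the
#' trapezoid area under the full ROC curve with tied scores traversed
#' diagonally.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Vector of +1 / -1 (or logical), one per score; both classes
#'   must be present.
#' @return ROC score in `[0, 1]`.
#' @export
#' @examples
#' roc_score(c(2, 1, 0), c(1, 1, -1))        # 1
#' roc_score(c(0.9, 0.7, 0.8), c(1, 1, -1))  # 0.5
roc_score <- function(scores, labels) {
  labels <- normalize_labels(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_score needs both positive and negative labels", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC50 score
#'
#' Area under the ROC curve truncated at the 50th false positive, normalised
#' by `n_pos * min(50, n_neg)` so the score lies in `[0, 1]`: 1 when every
#' positive outranks the first 50 false positives, 0 when 50 negatives outrank
#' every positive. When `n_neg <= 50` the truncation is vacuous and the ROC50
#' equals the ROC score. Tied scores are traversed diagonally.
#'
#' @inheritParams roc_score
#' @param n_fp Number of false positives at which to truncate (default 50).
#' @return ROC50 score in `[0, 1]`.
#' @export
roc50_score <- function(scores, labels, n_fp = 50L) {
  labels <- normalize_labels(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc50_score needs both positive and negative labels", call. = FALSE)
  }
  fp_cap <- min(n_fp, n_neg)
  # walk tie groups in decreasing score order, accumulating trapezoid area
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- 0; fp <- 0; area <- 0
  for (g in seq_len(max(grp))) {
    in_g <- grp == g
    dtp <- sum(y[in_g] == 1)
    dfp <- sum(y[in_g] == -1)
    if (fp + dfp <= fp_cap) {
      area <- area + dfp * (tp + dtp / 2)
      tp <- tp + dtp
      fp <- fp + dfp
    } else {
      frac <- (fp_cap - fp) / dfp
      area <- area + frac * dfp * (tp + frac * dtp / 2)
      fp <- fp_cap
      break
    }
    if (fp == fp_cap) break
  }
  area / (n_pos * fp_cap)
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 / -1", call. = FALSE)
  labels
}

#' Points of the (truncated) ROC curve
#'
#' Exports the (false positive, true positive) count pairs of the ranked-list
#' ROC curve, for plotting or external analysis.
#'
#' @inheritParams roc_score
#' @return Data frame with columns `fp` and `tp`.
#' @export
roc_points <- function(scores, labels) {
  labels <- normalize_labels(labels)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  tp <- cumsum(tapply(y == 1, grp, sum))
  fp <- cumsum(tapply(y == -1, grp, sum))
  data.frame(fp = c(0, unname(fp)), tp = c(0, unname(tp)))
}

#' Define a family train/test split
#'
#' The benchmark protocol holds out one family: its members are positive test
#' samples, other members of the same superfamily are positive training
#' samples, and sequences from outside the superfamily provide the negative
#' train/test sets. The four id lists must be pairwise disjoint.
#'
#' @param family_id Family identifier.
#' @param positive_train,positive_test,negative_train,negative_test Character
#'   vectors of sequence ids.
#' @return Object of class `family_split`.
#' @export
family_split <- function(family_id, positive_train, positive_test,
                         negative_train, negative_test) {
  lists <- list(positive_train = as.character(positive_train),
                positive_test = as.character(positive_test),
                negative_train = as.character(negative_train),
                negative_test = as.character(negative_test))
  all_ids <- unlist(lists, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("family split id lists must be pairwise disjoint; duplicated: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "), call. = FALSE)
  }
  structure(c(list(family_id = as.character(family_id)), lists),
            class = "family_split")
}

#' Read / write family split files
#'
#' Plain-text split format: lines of `<id> <role>` where role is one of
#' `pos-train`, `pos-test`, `neg-train`, `neg-test`; `#` comments and a
#' `family: <id>` line are allowed.
#'
#' @param path File path.
#' @param family_id Family id; defaults to the `family:` line or the file name.
#' @return A [family_split()].
#' @export
read_family_split <- function(path, family_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  fam_line <- grep("^family:", lines, value = TRUE)
  if (is.null(family_id)) {
    family_id <- if (length(fam_line)) trimws(sub("^family:", "", fam_line[1]))
                 else sub("\\.[^.]*$", "", basename(path))
  }
  lines <- lines[!grepl("^\\s*(#|family:|$)", lines)]
  tk <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(vapply(tk, length, integer(1)) != 2L)
  if (length(bad)) stop("malformed split line in ", path, ": ", lines[bad[1]], call. = FALSE)
  ids <- vapply(tk, `[`, character(1), 1L)
  role <- vapply(tk, `[`, character(1), 2L)
  ok <- c("pos-train", "pos-test", "neg-train", "neg-test")
  if (!all(role %in% ok)) {
    stop("unknown role '", setdiff(role, ok)[1], "' in ", path, call. = FALSE)
  }
  family_split(family_id,
               positive_train = ids[role == "pos-train"],
               positive_test = ids[role == "pos-test"],
               negative_train = ids[role == "neg-train"],
               negative_test = ids[role == "neg-test"])
}

#' @rdname read_family_split
#' @param split A [family_split()].
#' @export
write_family_split <- function(split, path) {
  stopifnot(inherits(split, "family_split"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("family:", split$family_id), con)
  roles <- c(positive_train = "pos-train", positive_test = "pos-test",
             negative_train = "neg-train", negative_test = "neg-test")
  for (f in names(roles)) {
    if (length(split[[f]])) writeLines(paste(split[[f]], roles[[f]]), con)
  }
  invisible(path)
}

#' Run the per-family benchmark protocol
#'
#' For each family split: build feature vectors for the train and test ids,
#' train the one-vs-rest classifier on the training ids, score the test ids,
#' and compute the family's ROC and ROC50. Averages across families are
#' unweighted.
#'
#' @param splits A [family_split()] or list of them.
#' @param sequences Named character vector of residue strings covering all ids
#'   (required for `mode = "dr"`).
#' @param profiles Named list of [frequency_profile()]s covering all ids
#'   (required for `mode = "dt"`).
#' @param mode `"dt"` (Top-1-gram features from profiles, the default) or
#'   `"dr"` (native residue features).
#' @param d_max Distance threshold.
#' @param config A [classifier_config()].
#' @return Data frame of class `benchmark_result` with one row per family
#'   (`family_id`, `roc`, `roc50`, `n_pos`, `n_neg`) and attributes
#'   `mean_roc`, `mean_roc50`.
#' @export
run_benchmark <- function(splits, sequences = NULL, profiles = NULL,
                          mode = c("dt", "dr"), d_max = 150L,
                          config = classifier_config()) {
  mode <- match.arg(mode)
  if (inherits(splits, "family_split")) splits <- list(splits)
  featurize <- make_featurizer(mode, sequences, profiles, d_max)

  rows <- lapply(splits, function(sp) {
    stopifnot(inherits(sp, "family_split"))
    if (length(sp$positive_test) == 0L || length(sp$negative_test) == 0L) {
      stop("family ", sp$family_id, ": test sets must be nonempty", call. = FALSE)
    }
    train_ids <- c(sp$positive_train, sp$negative_train)
    test_ids <- c(sp$positive_test, sp$negative_test)
    check_ids_available(c(train_ids, test_ids), mode, sequences, profiles, sp$family_id)
    x_train <- t(vapply(train_ids, featurize, numeric(feature_dimension(d_max))))
    x_test <- t(vapply(test_ids, featurize, numeric(feature_dimension(d_max))))
    y_train <- c(rep(1, length(sp$positive_train)), rep(-1, length(sp$negative_train)))
    y_test <- c(rep(1, length(sp$positive_test)), rep(-1, length(sp$negative_test)))
    model <- train_family_classifier(x_train, y_train, ids = train_ids,
                                     config = config, d_max = d_max)
    s <- score(model, x_test)
    data.frame(family_id = sp$family_id,
               roc = roc_score(s, y_test),
               roc50 = roc50_score(s, y_test),
               n_pos = length(sp$positive_test),
               n_neg = length(sp$negative_test),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "mean_roc") <- mean(res$roc)
  attr(res, "mean_roc50") <- mean(res$roc50)
  attr(res, "mode") <- mode
  attr(res, "d_max") <- as.integer(d_max)
  class(res) <- c("benchmark_result", class(res))
  res
}

make_featurizer <- function(mode, sequences, profiles, d_max) {
  if (mode == "dr") {
    if (is.null(sequences)) stop("mode 'dr' requires sequences", call. = FALSE)
    function(id) as.numeric(dr_features(sequences[[id]], d_max = d_max, id = id))
  } else {
    if (is.null(profiles)) stop("mode 'dt' requires profiles", call. = FALSE)
    function(id) as.numeric(dt_features(profiles[[id]], d_max = d_max))
  }
}

check_ids_available <- function(ids, mode, sequences, profiles, family_id) {
  pool <- if (mode == "dr") names(sequences) else names(profiles)
  missing <- setdiff(ids, pool)
  if (length(missing)) {
    stop(sprintf("family %s: no %s available for id(s) %s", family_id,
                 if (mode == "dr") "sequence" else "profile",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d families, mode %s, d_max = %d\n",
              nrow(x), attr(x, "mode"), attr(x, "d_max")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Average ROC %.4f, average ROC50 %.4f\n",
              attr(x, "mean_roc"), attr(x, "mean_roc50")))
  invisible(x)
}

#' Write benchmark results as TSV
#'
#' One row per family plus a `summary` row holding the unweighted averages.
#'
#' @param res A `benchmark_result` from [run_benchmark()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(res, path) {
  out <- rbind(data.frame(family_id = res$family_id, roc = res$roc,
                          roc50 = res$roc50, n_pos = res$n_pos, n_neg = res$n_neg),
               data.frame(family_id = "summary", roc = attr(res, "mean_roc"),
                          roc50 = attr(res, "mean_roc50"),
                          n_pos = sum(res$n_pos), n_neg = sum(res$n_neg)))
  utils::write.table(format(out, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
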