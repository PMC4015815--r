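#' Fit a distance-pair SVM family classifier
#'
#' The front door of the package: converts protein sequences (mode `"dr"`) or
#' frequency profiles (mode `"dt"`, via their Top-1-gram sequences) into
#' distance feature vectors — ordered symbol-pair counts at every positional
#' offset up to `d_max`, plus the composition block — and trains a one-vs-rest
#' soft-margin SVM on the unit-normalised vectors. The fitted object carries
#' the explicit discriminant weight vector `w = M alpha`, so feature
#' importance is directly inspectable.
#'
#' @param x Named character vector of residue strings (`mode = "dr"`), named
#'   list of [frequency_profile()]s (`mode = "dt"`), or a numeric feature
#'   matrix with one vector per row (mode ignored).
#' @param labels Vector of +1 / -1 (or logical), one element per sequence.
#' @param mode `"dt"` or `"dr"`. Default `"dt"`, the profile-based method.
#' @param d_max Distance threshold; default 150, the standard operating point
#'   (feature dimension 60020).
#' @param config A [classifier_config()].
#' @return Object of class `dsvm`: the `trained_model`, the
#'   `discriminant_weights` `w`, `mode`, `d_max`, the call, and training-set
#'   summary statistics.
#' @seealso [predict.dsvm()], [coef.dsvm()], [plot.dsvm()], [run_benchmark()]
#' @export
#' @examples
#' fam <- generate_family(synthetic_family_config(seed = 7))
#' tr <- c(fam$split$positive_train, fam$split$negative_train)
#' y <- ifelse(tr %in% fam$split$positive_train, 1, -1)
#' fit <- dsvm(fam$sequences[tr], y, mode = "dr", d_max = 10)
#' fit
#' scores <- predict(fit, fam$sequences[fam$split$positive_test])
dsvm <- function(x, labels, mode = c("dt", "dr"), d_max = 150L,
                 config = classifier_config()) {
  mode <- match.arg(mode)
  cl <- match.call()
  labels <- normalize_labels(labels)
  if (is.matrix(x)) {
    if (ncol(x) != feature_dimension(d_max)) {
      stop("feature matrix has ", ncol(x), " columns; expected ",
           feature_dimension(d_max), " for d_max = ", d_max, call. = FALSE)
    }
    X <- x
    ids <- rownames(x)
  } else {
    X <- featurize_inputs(x, mode, d_max)
    ids <- names(x)
  }
  model <- train_family_classifier(X, labels, ids = ids, config = config,
                                   d_max = d_max)
  w <- if (config$kernel == "linear") discriminant_weights(model) else NULL
  train_scores <- score(model, X)
  structure(list(model = model, w = w, mode = mode, d_max = as.integer(d_max),
                 call = cl,
                 train_roc = roc_score(train_scores, labels),
                 n_pos = sum(labels == 1), n_neg = sum(labels == -1)),
            class = "dsvm")
}

featurize_inputs <- function(x, mode, d_max) {
  if (mode == "dt") {
    if (!is.list(x) || !all(vapply(x, inherits, logical(1), "frequency_profile"))) {
      stop("mode 'dt' needs a list of frequency_profile objects", call. = FALSE)
    }
    t(vapply(x, function(p) as.numeric(dt_features(p, d_max = d_max)),
             numeric(feature_dimension(d_max))))
  } else {
    if (!is.character(x)) stop("mode 'dr' needs a character vector of sequences",
                               call. = FALSE)
    t(vapply(seq_along(x), function(i)
      as.numeric(dr_features(x[[i]], d_max = d_max, id = names(x)[i])),
      numeric(feature_dimension(d_max))))
  }
}

#' @export
print.dsvm <- function(x, ...) {
  cat(sprintf("Distance-pair SVM (%s mode), d_max = %d, %d features\n",
              toupper(x$mode), x$d_max, feature_dimension(x$d_max)))
  cat(sprintf("Training: %d positive, %d negative; training ROC %.3f\n",
              x$n_pos, x$n_neg, x$train_roc))
  invisible(x)
}

#' @export
summary.dsvm <- function(object, n_top = 5L, ...) {
  imp <- if (!is.null(object$w)) pair_l2_norms(object$w) else NULL
  out <- list(fit = object, importance = imp, n_top = n_top)
  class(out) <- "summary.dsvm"
  out
}

#' @export
print.summary.dsvm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Support vectors: %d of %d\n",
              sum(x$fit$model$alpha != 0), length(x$fit$model$alpha)))
  if (!is.null(x$importance)) {
    p <- x$importance$pairs
    top <- order(p, decreasing = TRUE)[seq_len(x$n_top)]
    a <- aa_alphabet()[(top - 1) %% 20 + 1]
    b <- aa_alphabet()[(top - 1) %/% 20 + 1]
    cat("Most discriminative ordered pairs (L2-norm over distances):\n")
    for (k in seq_along(top)) {
      cat(sprintf("  (%s, %s)  %.4g\n", a[k], b[k], p[top[k]]))
    }
  }
  invisible(x)
}

#' Model coefficients: the discriminant weight vector
#'
#' @param object A fitted [dsvm()] model (linear kernel).
#' @param ... Unused.
#' @return The `discriminant_weights` vector `w = M alpha`.
#' @export
coef.dsvm <- function(object, ...) {
  if (is.null(object$w)) stop("coefficients are only defined for the linear kernel",
                              call. = FALSE)
  object$w
}

#' Score new proteins with a fitted distance-pair SVM
#'
#' @param object A fitted [dsvm()] model.
#' @param newdata Residue strings (`mode = "dr"`), list of profiles
#'   (`mode = "dt"`), or a feature matrix of matching dimension.
#' @param ... Unused.
#' @return Named numeric vector of discriminative scores; higher = more likely
#'   a family member.
#' @export
predict.dsvm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    featurize_inputs(newdata, object$mode, object$d_max)
  s <- score(object$model, X)
  names(s) <- if (is.matrix(newdata)) rownames(newdata) else names(newdata)
  s
}

#' Plot feature importance of a fitted distance-pair SVM
#'
#' `type = "importance"` draws the 20 x 20 heatmap of per-pair L2-norms
#' (x-axis: first symbol of the ordered pair, y-axis: second); `type =
#' "distance"` draws the signed per-distance weight profile of one pair.
#'
#' @param x A fitted [dsvm()] model (linear kernel).
#' @param type `"importance"` or `"distance"`.
#' @param pair Length-2 symbol pair for `type = "distance"`.
#' @param ... Passed to the underlying graphics call.
#' @return `x`, invisibly.
#' @export
plot.dsvm <- function(x, type = c("importance", "distance"),
                      pair = c("G", "G"), ...) {
  type <- match.arg(type)
  w <- coef(x)
  if (type == "importance") {
    imp <- pair_l2_norms(w)
    graphics::image(1:20, 1:20, imp$pairs, axes = FALSE,
                    xlab = "first symbol", ylab = "second symbol",
                    main = "Pair discriminative power (L2-norm)", ...)
    graphics::axis(1, at = 1:20, labels = aa_alphabet(), cex.axis = 0.7)
    graphics::axis(2, at = 1:20, labels = aa_alphabet(), cex.axis = 0.7, las = 1)
  } else {
    prof <- pair_distance_profile(w, pair[1], pair[2])
    graphics::plot(seq_along(prof), prof, type = "h",
                   xlab = "distance d", ylab = "discriminant weight",
                   main = sprintf("Pair (%s, %s) weight by distance",
                                  pair[1], pair[2]), ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
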