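#' Scale a feature vector to unit Euclidean norm
#'
#' Length normalisation removes the dependence of raw pair counts on sequence
#' length before SVM training. The all-zero vector is returned unchanged.
#'
#' @param v Numeric vector.
#' @return Numeric vector with `sqrt(sum(v^2)) == 1` (or all zeros).
#' @export
normalize_vector <- function(v) {
  nrm <- sqrt(sum(as.numeric(v)^2))
  if (nrm == 0) return(as.numeric(v))
  out <- as.numeric(v) / nrm
  attributes(out) <- attributes(v)
  out
}

#' Classifier configuration
#'
#' Defaults: linear kernel on unit-L2-normalised count vectors, soft margin
#' with cost 1, the minority (positive) class weighted by `n_neg / n_pos`, and
#' a tight solver tolerance so retraining and sample-order permutations leave
#' scores stable to well below 1e-6.
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost Soft-margin regularisation constant C.
#' @param class_weight `"balanced"` (positive-class weight `n_neg / n_pos`) or
#'   a named numeric vector `c(pos = ..., neg = ...)`.
#' @param normalize Unit-normalise feature vectors before training/scoring.
#' @param gamma RBF width (ignored for the linear kernel).
#' @param tolerance Dual-solver termination tolerance.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(kernel = c("linear", "rbf"), cost = 1,
                              class_weight = "balanced", normalize = TRUE,
                              gamma = 1, tolerance = 1e-7) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, gamma > 0, tolerance > 0)
  structure(list(kernel = kernel, cost = cost, class_weight = class_weight,
                 normalize = normalize, gamma = gamma, tolerance = tolerance),
            class = "classifier_config")
}

kernel_matrix <- function(config, X, Y) {
  # rows of X against rows of Y
  if (config$kernel == "linear") return(X %*% t(Y))
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  exp(-config$gamma * pmax(d2, 0))
}

#' Train a one-vs-rest family classifier
#'
#' Fits a soft-margin SVM to labelled feature vectors (the quadratic program
#' is solved by libsvm via \pkg{e1071}) and repackages the solution as an
#' explicit kernel expansion: label-signed dual coefficients `alpha` over all
#' training samples, a bias, and the (normalised) training matrix. All scoring
#' in this package goes through that expansion, so the fitted object is
#' self-contained and the discriminant weight vector `w = M alpha` is exact.
#'
#' @param x Numeric matrix, one feature vector per row (consistent `d_max`),
#'   or a list of vectors from [build_feature_vector()].
#' @param labels Vector of +1 / -1, one per row; both classes required.
#' @param ids Optional character ids, one per row (must be unique).
#' @param config A [classifier_config()].
#' @param d_max Feature distance threshold, stored for dimension checks;
#'   inferred from vector attributes when `x` is a list.
#' @return Object of class `trained_model`: `alpha` (length N, `>= 0` on
#'   positive samples, `<= 0` on negative), `bias`, `X` (training matrix as
#'   scored), `labels`, `ids`, `config`, `d_max`.
#' @export
train_family_classifier <- function(x, labels, ids = NULL,
                                    config = classifier_config(), d_max = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    if (is.null(d_max)) d_max <- attr(x[[1]], "d_max")
    if (is.null(ids)) {
      nm <- vapply(x, function(v) as.character(attr(v, "id") %||% NA), character(1))
      if (!anyNA(nm)) ids <- nm
    }
    x <- do.call(rbind, lapply(x, as.numeric))
  }
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  if (nrow(x) != length(labels)) stop("need one label per row of x", call. = FALSE)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1 or -1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training requires both a positive and a negative class", call. = FALSE)
  }
  if (!is.null(ids) && anyDuplicated(ids)) stop("duplicate training ids", call. = FALSE)

  if (config$normalize) x <- t(apply(x, 1, normalize_vector))

  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  cw <- if (identical(config$class_weight, "balanced")) {
    c(pos = n_neg / n_pos, neg = 1)
  } else if (is.numeric(config$class_weight)) {
    config$class_weight
  } else c(pos = 1, neg = 1)

  y <- factor(ifelse(labels == 1, "pos", "neg"), levels = c("pos", "neg"))
  fit <- e1071::svm(
    x, y,
    scale = FALSE,
    type = "C-classification",
    kernel = if (config$kernel == "linear") "linear" else "radial",
    gamma = config$gamma,
    cost = config$cost,
    class.weights = cw,
    tolerance = config$tolerance,
    shrinking = FALSE
  )

  alpha <- numeric(nrow(x))
  alpha[fit$index] <- as.numeric(fit$coefs)  # y_i * alpha_i relative to level 1
  bias <- -fit$rho
  # orient so that higher score = positive class, independent of libsvm's
  # internal level bookkeeping
  if (sign_check(alpha, bias, x, labels, config) < 0) {
    alpha <- -alpha
    bias <- -bias
  }
  structure(list(alpha = alpha, bias = bias, X = x, labels = labels,
                 ids = ids, config = config,
                 d_max = if (is.null(d_max)) NA_integer_ else as.integer(d_max)),
            class = "trained_model")
}

# +1 if the kernel expansion already scores positives above negatives
sign_check <- function(alpha, bias, X, labels, config) {
  s <- as.numeric(kernel_matrix(config, X, X) %*% alpha) + bias
  if (mean(s[labels == 1]) >= mean(s[labels == -1])) 1 else -1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("Family SVM (%s kernel): %d training samples (%d pos / %d neg), %d support vectors\n",
              x$config$kernel, length(x$labels), sum(x$labels == 1),
              sum(x$labels == -1), sum(x$alpha != 0)))
  if (!is.na(x$d_max)) cat(sprintf("Feature space: d_max = %d (dimension %d)\n",
                                   x$d_max, ncol(x$X)))
  invisible(x)
}

#' Discriminative score of a test vector
#'
#' Computes the SVM decision value `sum_i alpha_i K(x_i, v) + bias`; higher
#' scores indicate the positive class. Test vectors receive the same unit
#' normalisation as the training vectors.
#'
#' @param model A `trained_model`.
#' @param v Numeric feature vector, or a matrix with one vector per row.
#' @return Numeric score(s).
#' @export
score <- function(model, v) {
  stopifnot(inherits(model, "trained_model"))
  V <- if (is.matrix(v)) v else matrix(as.numeric(v), nrow = 1)
  if (ncol(V) != ncol(model$X)) {
    stop(sprintf("feature dimension mismatch: model %d, input %d",
                 ncol(model$X), ncol(V)), call. = FALSE)
  }
  if (model$config$normalize) V <- t(apply(V, 1, normalize_vector))
  as.numeric(kernel_matrix(model$config, V, model$X) %*% model$alpha) + model$bias
}
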