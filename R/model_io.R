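MODEL_FORMAT_VERSION <- "1.0"

#' Save / load a trained family classifier
#'
#' The model file is a versioned, self-describing JSON archive storing the
#' label-signed dual coefficients, bias, configuration, `d_max`, training ids
#' and the training matrix of the kernel expansion (plus the explicit weight
#' vector for linear kernels), so a loaded model scores identically to the
#' original.
#'
#' @param model A `trained_model` from [train_family_classifier()] or a
#'   fitted [dsvm()] object.
#' @param path File path (`.json`).
#' @return `save_model()` returns `path` invisibly; `load_model()` returns a
#'   `trained_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "dsvm")) model <- model$model
  stopifnot(inherits(model, "trained_model"))
  obj <- list(
    format = "distsvm-model",
    version = MODEL_FORMAT_VERSION,
    d_max = if (!is.na(model$d_max)) model$d_max,
    config = unclass(model$config),
    bias = model$bias,
    alpha = model$alpha,
    labels = model$labels,
    ids = model$ids,
    X = model$X,
    w = if (model$config$kernel == "linear")
      as.numeric(discriminant_weights(model)) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "distsvm-model")) {
    stop("not a distsvm model file: ", path, call. = FALSE)
  }
  cfg <- do.call(classifier_config, obj$config[c("kernel", "cost", "normalize",
                                                 "gamma", "tolerance")])
  cfg$class_weight <- obj$config$class_weight
  structure(list(alpha = as.numeric(obj$alpha), bias = obj$bias,
                 X = as.matrix(obj$X), labels = as.numeric(obj$labels),
                 ids = obj$ids, config = cfg,
                 d_max = if (is.null(obj$d_max) || !length(obj$d_max))
                   NA_integer_ else as.integer(obj$d_max)),
            class = "trained_model")
}
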