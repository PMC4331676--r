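#' Save and load trained SVM models
#'
#' Models are serialized as a single self-describing JSON bundle: the
#' descriptor schema header (scheme, LG), hyperparameters `(C, gamma)`,
#' support vectors (row-major), dual coefficients, bias, optional min–max
#' scaling, and a fingerprint of the training set (sample count and feature
#' dimension). Full numeric precision is retained, so save/load round-trips
#' decision values exactly.
#'
#' @param model A `dt_svm` model.
#' @param path Output path.
#' @return `path` invisibly (`write_model`); a `dt_svm` (`read_model`).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "dt_svm"))
  schema <- model$schema
  obj <- list(
    format = "pssmdt-svm-1",
    scheme = if (is.null(schema)) NULL else attr(schema, "scheme"),
    LG = if (is.null(schema)) NULL else attr(schema, "LG"),
    C = model$C, gamma = model$gamma, bias = model$bias,
    n_train = model$n_train,
    n_features = ncol(model$support_vectors),
    support_index = model$support_index,
    dual_coefficients = model$dual_coefficients,
    support_vectors = as.vector(t(model$support_vectors)),
    scaling = model$scaling)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null", null = "null"), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (!identical(obj$format, "pssmdt-svm-1")) {
    abort(sprintf("'%s' is not a pssmdt SVM model bundle.", path))
  }
  sv <- matrix(obj$support_vectors, ncol = obj$n_features, byrow = TRUE)
  schema <- NULL
  if (!is.null(obj$scheme)) {
    schema <- descriptor_schema(obj$scheme,
                                LG = if (is.null(obj$LG) || is.na(obj$LG)) NULL else obj$LG)
    colnames(sv) <- schema$name
  }
  scaling <- obj$scaling
  scaling <- if (length(scaling$lo) > 0) {
    list(lo = scaling$lo, span = scaling$span)
  } else NULL
  structure(list(
    support_vectors = sv,
    dual_coefficients = obj$dual_coefficients,
    support_index = obj$support_index,
    bias = obj$bias, C = obj$C, gamma = obj$gamma,
    scaling = scaling, schema = schema, n_train = obj$n_train
  ), class = "dt_svm")
}
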