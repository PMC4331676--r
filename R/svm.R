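#' Train a soft-margin RBF-kernel SVM on an encoded dataset
#'
#' Solves the soft-margin dual for the radial-basis-function kernel
#' `K(x, y) = exp(-gamma * ||x - y||^2)` at penalty `C`, via the LIBSVM
#' solver (through \pkg{e1071}). The returned model stores the support
#' vectors, dual coefficients `alpha_i * y_i`, bias `b` and the descriptor
#' schema, with the sign convention that the decision function
#' `f(x) = sum_i (alpha_i y_i) K(s_i, x) + b` is positive for the +1 class.
#' Training is deterministic given the data and `(C, gamma)`.
#'
#' Features are used raw by default. Min–max scaling fitted on the training
#' data is available via `scale_features = TRUE` (the scaler is stored in the
#' model and re-applied at prediction time); raw squared-profile features
#' have a large dynamic range, which the grid-searched `gamma` otherwise has
#' to absorb.
#'
#' @param data Encoded dataset tibble from [encode_profiles()] (columns `id`,
#'   `label`, then one column per descriptor), or any tibble with a `label`
#'   column over \{+1, -1\} and numeric features.
#' @param C Penalty parameter (positive).
#' @param gamma RBF kernel width (positive).
#' @param scale_features Fit and apply a per-feature min–max scaler.
#' @param tolerance Solver termination tolerance (passed to LIBSVM).
#' @return An object of class `dt_svm`.
#' @export
svm_train <- function(data, C = 1, gamma = NULL, scale_features = FALSE,
                      tolerance = 1e-3) {
  x <- feature_matrix(data)
  y <- dataset_labels(data)
  if (length(unique(y)) < 2L) {
    abort("Training data must contain both classes (+1 and -1).")
  }
  stopifnot(C > 0)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  stopifnot(gamma > 0)

  scaling <- NULL
  if (scale_features) {
    scaling <- fit_minmax(x)
    x <- apply_minmax(x, scaling)
  }

  fit <- e1071::svm(x = x, y = factor(y, levels = c(1, -1)),
                    type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE,
                    tolerance = tolerance)
  # e1071 reports decision values as positive for the class named first in
  # the "<a>/<b>" column label; flip so positive always means +1.
  dv <- attr(predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (startsWith(colnames(dv)[[1]], "1/")) 1 else -1

  structure(list(
    support_vectors = fit$SV,
    dual_coefficients = flip * as.numeric(fit$coefs),
    support_index = fit$index,
    bias = -flip * fit$rho,
    C = C, gamma = gamma,
    scaling = scaling,
    schema = schema_of(data),
    n_train = nrow(x)
  ), class = "dt_svm")
}

dataset_labels <- function(data) {
  if (!"label" %in% names(data)) {
    abort("Dataset has no `label` column.")
  }
  y <- as.numeric(data$label)
  if (!all(y %in% c(-1, 1))) abort("Labels must lie in {+1, -1}.")
  y
}

fit_minmax <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

apply_minmax <- function(x, scaling) {
  sweep(sweep(x, 2, scaling$lo), 2, scaling$span, "/")
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Decision values and labels for new samples
#'
#' Evaluates the kernel expansion `f(x) = sum_i (alpha_i y_i) K(s_i, x) + b`
#' for each row of `data` and assigns the label by sign, with the `f(x) = 0`
#' tie going to +1.
#'
#' @param object A `dt_svm` model.
#' @param data Encoded dataset tibble (or a single `feature_vector`); its
#'   schema must match the model's.
#' @param ... Unused.
#' @return A tibble with columns `id`, `decision_value`, `label`.
#' @export
predict.dt_svm <- function(object, data, ...) {
  if (inherits(data, "feature_vector")) {
    sch <- schema_of(data)
    data <- tibble::as_tibble(as.data.frame(t(unclass(data)),
                                            check.names = FALSE))
    attr(data, "schema") <- sch
  }
  check_model_schema(object, schema_of(data))
  x <- feature_matrix(data)
  if (ncol(x) != ncol(object$support_vectors)) {
    abort(sprintf("Model expects %d features, data has %d.",
                  ncol(object$support_vectors), ncol(x)))
  }
  if (!is.null(object$scaling)) x <- apply_minmax(x, object$scaling)
  f <- drop(rbf_kernel(x, object$support_vectors, object$gamma) %*%
              object$dual_coefficients) + object$bias
  tibble::tibble(
    id = if ("id" %in% names(data)) data$id else sprintf("x%03d", seq_len(nrow(x))),
    decision_value = f,
    label = ifelse(f >= 0, 1, -1))
}

check_model_schema <- function(model, schema) {
  if (is.null(model$schema) || is.null(schema)) return(invisible(TRUE))
  if (!same_schema(model$schema, schema)) {
    abort(sprintf("Schema mismatch: model was trained on %s but data is %s.",
                  describe_schema(model$schema), describe_schema(schema)))
  }
  invisible(TRUE)
}

#' @export
print.dt_svm <- function(x, ...) {
  cat(sprintf("<dt_svm> RBF SVM: C = %g, gamma = %g, %d support vectors / %d samples\n",
              x$C, x$gamma, nrow(x$support_vectors), x$n_train))
  if (!is.null(x$schema)) cat(" schema:", describe_schema(x$schema), "\n")
  invisible(x)
}

#' @export
tidy.dt_svm <- function(x, ...) {
  tibble::tibble(
    support_vector = seq_along(x$dual_coefficients),
    train_row = x$support_index,
    dual_coefficient = x$dual_coefficients)
}

#' @export
glance.dt_svm <- function(x, ...) {
  tibble::tibble(
    C = x$C, gamma = x$gamma,
    n_support = length(x$dual_coefficients),
    n_train = x$n_train,
    bias = x$bias,
    scaled = !is.null(x$scaling))
}

#' Default LIBSVM-style hyperparameter grids
#'
#' The conventional exponential grids: `C` over `2^(-5), 2^(-3), ..., 2^15`
#' and `gamma` over `2^(-15), 2^(-13), ..., 2^3`.
#' @return A list with `C` and `gamma` numeric vectors.
#' @export
default_grids <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Grid search for (C, gamma) by stratified k-fold cross-validation
#'
#' Evaluates every `(C, gamma)` pair by mean accuracy over `folds`
#' stratified folds (fold assignment drawn once from `seed`) and returns the
#' maximiser. Ties break to the smaller `C`, then the smaller `gamma`.
#'
#' @inheritParams svm_train
#' @param C_grid,gamma_grid Candidate values (non-empty numeric vectors).
#' @param folds Number of cross-validation folds (>= 2); every class must
#'   have at least `folds` members.
#' @param seed Integer seed controlling the fold assignment.
#' @return A list with `C`, `gamma`, `accuracy` (the winning mean CV
#'   accuracy) and `cv_table`, a tibble of all grid points.
#' @export
grid_search <- function(data, C_grid = default_grids()$C,
                        gamma_grid = default_grids()$gamma, folds = 5,
                        seed = 1, scale_features = FALSE) {
  stopifnot(folds >= 2, length(C_grid) >= 1, length(gamma_grid) >= 1)
  y <- dataset_labels(data)
  fold_id <- stratified_folds(y, folds, seed)
  grid <- tidyr::crossing(C = sort(C_grid), gamma = sort(gamma_grid))
  acc <- purrr::pmap_dbl(grid, function(C, gamma) {
    cv_accuracy(data, y, fold_id, C, gamma, scale_features)
  })
  cv_table <- dplyr::mutate(grid, accuracy = acc)
  best <- cv_table |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$C, .data$gamma) |>
    dplyr::slice(1)
  list(C = best$C, gamma = best$gamma, accuracy = best$accuracy,
       cv_table = cv_table, folds = folds, seed = seed)
}

# Class-stratified fold labels, deterministic given the seed.
stratified_folds <- function(y, folds, seed) {
  counts <- table(y)
  if (any(counts < folds)) {
    abort(sprintf(
      "Every class needs at least %d members for %d-fold CV (class sizes: %s).",
      folds, folds, paste(counts, collapse = ", ")))
  }
  fold_id <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

cv_accuracy <- function(data, y, fold_id, C, gamma, scale_features) {
  correct <- 0L
  for (k in sort(unique(fold_id))) {
    train <- data[fold_id != k, , drop = FALSE]
    attr(train, "schema") <- schema_of(data)
    test <- data[fold_id == k, , drop = FALSE]
    attr(test, "schema") <- schema_of(data)
    model <- svm_train(train, C = C, gamma = gamma,
                       scale_features = scale_features)
    pred <- predict(model, test)
    correct <- correct + sum(pred$label == y[fold_id == k])
  }
  correct / length(y)
}
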