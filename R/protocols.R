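new_evaluation_report <- function(predictions, protocol, C, gamma, seed = NA) {
  counts <- confusion_counts(predictions$truth, predictions$label)
  metrics <- compute_metrics(counts)
  roc <- roc_auc(predictions$decision_value, predictions$truth)
  structure(list(
    predictions = predictions,
    counts = counts,
    metrics = metrics,
    roc = roc$roc,
    auc = roc$auc,
    protocol = protocol,
    C = C, gamma = gamma,
    seed = seed
  ), class = "evaluation_report")
}

#' Jackknife (leave-one-out) evaluation
#'
#' Runs n train/predict rounds, each holding out exactly one sample and
#' training the RBF SVM at fixed `(C, gamma)` on the remaining n - 1; every
#' sample is tested exactly once. The pooled held-out decision values and
#' labels feed the confusion metrics and the ROC/AUC. Hyperparameters are
#' chosen once beforehand (typically by [grid_search()] on the full set) and
#' held fixed across rounds — the protocol the method prescribes, which is
#' mildly optimistic since the held-out sample participated in tuning.
#'
#' @inheritParams svm_train
#' @return An `evaluation_report` (see [tidy.evaluation_report()]).
#' @export
jackknife <- function(data, C = 1, gamma = NULL, scale_features = FALSE) {
  y <- dataset_labels(data)
  n <- length(y)
  if (n < 3) abort("Jackknife needs at least 3 samples.")
  if (any(table(y) < 2)) {
    abort("Jackknife needs at least 2 members per class so no training fold collapses to one class.")
  }
  schema <- schema_of(data)
  rounds <- lapply(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    attr(train, "schema") <- schema
    test <- data[i, , drop = FALSE]
    attr(test, "schema") <- schema
    model <- svm_train(train, C = C, gamma = gamma,
                       scale_features = scale_features)
    predict(model, test)
  })
  predictions <- dplyr::bind_rows(rounds)
  predictions$truth <- y
  new_evaluation_report(predictions, "jackknife", C, gamma)
}

#' Independent-test evaluation
#'
#' Trains once on `train` and evaluates on the disjoint `test` set. Schemas
#' must match; overlapping ids raise a warning (sequence-identity screening
#' between the sets is the user's responsibility).
#'
#' @param train,test Encoded dataset tibbles with `label` columns.
#' @inheritParams svm_train
#' @return An `evaluation_report`.
#' @export
independent_test <- function(train, test, C = 1, gamma = NULL,
                             scale_features = FALSE) {
  if (nrow(test) == 0) abort("Independent test set is empty.")
  check_model_schema(list(schema = schema_of(train)), schema_of(test))
  overlap <- intersect(train$id, test$id)
  if (length(overlap) > 0) {
    warn(sprintf("Train and test sets share %d id(s) (e.g. %s); the test is not independent.",
                 length(overlap), overlap[[1]]))
  }
  model <- svm_train(train, C = C, gamma = gamma,
                     scale_features = scale_features)
  predictions <- predict(model, test)
  predictions$truth <- dataset_labels(test)
  new_evaluation_report(predictions, "independent", C, gamma)
}

#' Maximum-lag sweep under k-fold cross-validation
#'
#' For each candidate maximum lag `LG`, encodes the profiles with the
#' concatenated distance-transformation scheme, grid-searches `(C, gamma)`
#' by stratified `folds`-fold cross-validation, and reports the winning CV
#' accuracy and MCC. Hyperparameters are re-tuned per `LG` since each `LG`
#' changes the feature dimensionality. Deterministic given `seed`.
#'
#' @param profiles List of [pssm_profile()] objects; all longer than
#'   `max(LG_values)`.
#' @param labels Labels over \{+1, -1\}, one per profile.
#' @param LG_values Integer lags to sweep.
#' @param folds Cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param C_grid,gamma_grid Hyperparameter grids (see [grid_search()]).
#' @inheritParams svm_train
#' @return A tibble with one row per `LG`: `LG`, `dimension`, `C`, `gamma`,
#'   `acc`, `mcc`.
#' @export
lg_sweep <- function(profiles, labels, LG_values, folds = 5, seed = 1,
                     C_grid = default_grids()$C,
                     gamma_grid = default_grids()$gamma,
                     scale_features = FALSE) {
  check_labels(labels, length(profiles))
  lens <- vapply(profiles, profile_length, integer(1))
  if (min(lens) <= max(LG_values)) {
    abort(sprintf("All profile lengths must exceed max(LG_values) = %d (shortest is %d).",
                  max(LG_values), min(lens)))
  }
  purrr::map_dfr(sort(unique(as.integer(LG_values))), function(LG) {
    data <- encode_profiles(profiles, "dt", LG = LG, labels = labels)
    gs <- grid_search(data, C_grid = C_grid, gamma_grid = gamma_grid,
                      folds = folds, seed = seed,
                      scale_features = scale_features)
    cm <- kfold_metrics(data, gs$C, gs$gamma, folds, seed, scale_features)
    tibble::tibble(LG = LG, dimension = 400L * LG, C = gs$C, gamma = gs$gamma,
                   acc = cm$acc, mcc = cm$mcc)
  })
}

# Pooled k-fold confusion metrics at fixed hyperparameters, reusing the same
# seeded stratified fold assignment as the grid search.
kfold_metrics <- function(data, C, gamma, folds, seed, scale_features = FALSE) {
  y <- dataset_labels(data)
  fold_id <- stratified_folds(y, folds, seed)
  schema <- schema_of(data)
  preds <- numeric(length(y))
  for (k in sort(unique(fold_id))) {
    train <- data[fold_id != k, , drop = FALSE]
    attr(train, "schema") <- schema
    test <- data[fold_id == k, , drop = FALSE]
    attr(test, "schema") <- schema
    model <- svm_train(train, C = C, gamma = gamma,
                       scale_features = scale_features)
    preds[fold_id == k] <- predict(model, test)$label
  }
  compute_metrics(confusion_counts(y, preds))
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_report> protocol: %s  (C = %g, gamma = %g)\n",
              x$protocol, x$C, x$gamma))
  cat(sprintf(" n = %d  TP %d  FP %d  TN %d  FN %d\n",
              sum(unlist(x$counts)), m$TP, m$FP, m$TN, m$FN))
  cat(sprintf(" ACC %.2f%%  SN %.2f%%  SP %.2f%%  MCC %.3f  AUC %.2f%%\n",
              100 * m$acc, 100 * m$sn, 100 * m$sp, m$mcc, 100 * x$auc))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the per-sample held-out predictions; `glance()` returns
#' the one-row summary (counts, SN/SP/ACC as percentages, MCC, AUC).
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::as_tibble(x$predictions)
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    protocol = x$protocol, n = sum(unlist(x$counts)),
    TP = m$TP, FP = m$FP, TN = m$TN, FN = m$FN,
    sn_pct = round(100 * m$sn, 2), sp_pct = round(100 * m$sp, 2),
    acc_pct = round(100 * m$acc, 2), mcc = m$mcc,
    auc_pct = round(100 * x$auc, 2), C = x$C, gamma = x$gamma)
}

#' Plot the ROC curve of an evaluation report
#'
#' Sensitivity against 1 - specificity across the swept thresholds, with the
#' chance diagonal for reference.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate (1 - SP)",
                  y = "True positive rate (SN)",
                  title = sprintf("ROC (%s), AUC = %.3f",
                                  object$protocol, object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a maximum-lag sweep
#'
#' Accuracy and MCC as a function of the maximum lag, as returned by
#' [lg_sweep()].
#'
#' @param sweep Tibble from [lg_sweep()].
#' @return A ggplot object.
#' @export
plot_lg_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep[, c("LG", "acc", "mcc")],
                              c("acc", "mcc"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$LG, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Maximum lag LG", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize an evaluation report to JSON
#'
#' Writes the protocol, hyperparameters, confusion counts, metrics, AUC and
#' ROC points as a single JSON object. Deterministic given the report.
#'
#' @param report An `evaluation_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_report <- function(report, path = NULL) {
  m <- report$metrics
  obj <- list(
    protocol = report$protocol,
    C = report$C, gamma = report$gamma,
    counts = report$counts,
    sn_pct = round(100 * m$sn, 2), sp_pct = round(100 * m$sp, 2),
    acc_pct = round(100 * m$acc, 2),
    mcc = round(m$mcc, 4), auc_pct = round(100 * report$auc, 2),
    roc = list(fpr = report$roc$fpr, tpr = report$roc$tpr))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
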