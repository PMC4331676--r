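#' Discriminant weight vector of a trained SVM
#'
#' Projects a kernel-trained model back onto the input feature space as the
#' linear read-out `W = A' M`, where `A` holds the per-sample training
#' weights `alpha_i * y_i` (zero for non-support samples) and `M` is the
#' feature matrix of the training set: `W_k = sum_i (alpha_i y_i) M[i, k]`.
#' For an RBF model this is a first-order surrogate of the decision
#' function, not its true gradient; it is the conventional read-out for
#' ranking descriptors by discriminative contribution, and is linear in `A`.
#'
#' @param model A `dt_svm` trained on the dataset whose features are `data`.
#' @param data The encoded training dataset tibble (same rows, same order).
#' @return A tibble with one row per descriptor: `index`, `name`, `aa1`,
#'   `aa2`, `lg`, `weight`.
#' @export
discriminant_weights <- function(model, data) {
  M <- feature_matrix(data)
  if (!is.null(model$scaling)) M <- apply_minmax(M, model$scaling)
  check_model_schema(model, schema_of(data))
  if (max(model$support_index) > nrow(M) ||
      ncol(M) != ncol(model$support_vectors)) {
    abort(sprintf(
      "Dimension mismatch: model was trained on %d samples x %d features, data is %d x %d.",
      model$n_train, ncol(model$support_vectors), nrow(M), ncol(M)))
  }
  A <- numeric(nrow(M))
  A[model$support_index] <- model$dual_coefficients
  W <- unname(drop(crossprod(A, M)))
  schema <- schema_of(data)
  if (is.null(schema)) {
    schema <- tibble::tibble(index = seq_along(W),
                             name = colnames(M) %||% sprintf("f%d", seq_along(W)),
                             aa1 = NA_character_, aa2 = NA_character_,
                             lg = NA_integer_)
  }
  dplyr::mutate(schema, weight = W)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-pair discriminant weights
#'
#' Collapses a descriptor-level weight vector over a distance-transformation
#' schema into one non-negative weight per ordered amino-acid pair: the
#' quadratic sum, over that pair's lags, of the descriptor weights that are
#' strictly positive (descriptors loading on the positive, DNA-binding
#' class). Same-pair descriptors fill the matrix diagonal.
#'
#' @param weights Tibble from [discriminant_weights()] over an `sdt`, `ddt`
#'   or `dt` schema.
#' @return A tibble `aa1`, `aa2`, `weight`, sorted by weight descending
#'   (ranked pairs), with the full 20 x 20 matrix as attribute `"matrix"`.
#' @export
pair_discriminant_weights <- function(weights) {
  check_pair_schema(weights)
  pairs <- weights |>
    dplyr::group_by(.data$aa1, .data$aa2) |>
    dplyr::summarise(weight = sum(.data$weight[.data$weight > 0]^2),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$weight))
  mat <- matrix(0, 20, 20, dimnames = list(aa_alphabet, aa_alphabet))
  mat[cbind(match(pairs$aa1, aa_alphabet), match(pairs$aa2, aa_alphabet))] <-
    pairs$weight
  attr(pairs, "matrix") <- mat
  pairs
}

check_pair_schema <- function(weights) {
  need <- c("aa1", "aa2", "lg", "weight")
  if (!all(need %in% names(weights)) ||
      any(is.na(weights$aa1)) || any(is.na(weights$aa2))) {
    abort("Expected descriptor weights over a distance-transformation (pair, lag) schema.")
  }
  invisible(weights)
}

#' Per-lag discriminant weights of one amino-acid pair
#'
#' The raw (signed, unsquared) descriptor weights of one ordered pair in lag
#' order, i.e. one weight per `lg = 1..LG`. Squaring the positive entries
#' and summing reproduces that pair's entry in
#' [pair_discriminant_weights()].
#'
#' @inheritParams pair_discriminant_weights
#' @param pair Ordered amino-acid pair, e.g. `c("R", "R")`.
#' @return A tibble `lg`, `weight`.
#' @export
per_lag_weights <- function(weights, pair) {
  check_pair_schema(weights)
  if (length(pair) != 2L || !all(pair %in% aa_alphabet)) {
    abort(sprintf("`pair` must be two canonical amino-acid letters, got: %s.",
                  paste(pair, collapse = ", ")))
  }
  sub <- weights |>
    dplyr::filter(.data$aa1 == pair[[1]], .data$aa2 == pair[[2]]) |>
    dplyr::arrange(.data$lg)
  if (nrow(sub) == 0) {
    abort(sprintf("Pair (%s, %s) is not in this schema.", pair[[1]], pair[[2]]))
  }
  sub[, c("lg", "weight")]
}

#' Locate occurrences of a pair descriptor in a sequence
#'
#' All 1-based position pairs `(j, j + lg)` at which the sequence carries
#' the first amino acid of the pair at `j` and the second at `j + lg` —
#' literal residue-pair matches, used to map high-weight descriptors back
#' onto sequence regions.
#'
#' @param seq A sequence (list with `id`, `residues`), a [pssm_profile()],
#'   or a residue string.
#' @param pair Ordered amino-acid pair, e.g. `c("A", "R")`.
#' @param lg Lag (integer >= 1, smaller than the sequence length).
#' @return A tibble `pos1`, `pos2`; zero rows when the descriptor is absent.
#' @examples
#' locate_descriptor_occurrences("ARPR", c("A", "R"), 1)
#' @export
locate_descriptor_occurrences <- function(seq, pair, lg) {
  residues <- if (is.character(seq)) seq else seq$residues
  validate_residues(residues)
  if (length(pair) != 2L || !all(pair %in% aa_alphabet)) {
    abort("`pair` must be two canonical amino-acid letters.")
  }
  L <- nchar(residues)
  if (lg < 1 || lg != round(lg)) abort("`lg` must be an integer >= 1.")
  if (lg >= L) abort(sprintf("`lg` = %d must be smaller than the sequence length %d.", lg, L))
  chars <- strsplit(residues, "")[[1]]
  j <- which(chars[seq_len(L - lg)] == pair[[1]] &
             chars[seq_len(L - lg) + lg] == pair[[2]])
  tibble::tibble(pos1 = as.integer(j), pos2 = as.integer(j + lg))
}

#' Full discriminant analysis of a trained model
#'
#' Bundles [discriminant_weights()], [pair_discriminant_weights()] and the
#' per-lag tables of the `top_n` ranked pairs into one report.
#'
#' @inheritParams discriminant_weights
#' @param top_n Number of top-ranked pairs to expand per lag.
#' @return An object of class `discriminant_report`: list with `weights`,
#'   `pair_weights` (ranked tibble + matrix attribute), `ranked_pairs`
#'   (character vector "aa1-aa2"), `per_lag` (named list of tibbles).
#' @export
discriminant_report <- function(model, data, top_n = 4) {
  weights <- discriminant_weights(model, data)
  pairs <- pair_discriminant_weights(weights)
  top <- utils::head(pairs, top_n)
  per_lag <- purrr::map2(top$aa1, top$aa2,
                         function(a1, a2) per_lag_weights(weights, c(a1, a2)))
  names(per_lag) <- paste0(top$aa1, "-", top$aa2)
  structure(list(weights = weights, pair_weights = pairs,
                 ranked_pairs = paste0(pairs$aa1, "-", pairs$aa2),
                 per_lag = per_lag),
            class = "discriminant_report")
}

#' @export
print.discriminant_report <- function(x, ...) {
  cat("<discriminant_report>\n top pairs:",
      paste(utils::head(x$ranked_pairs, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.discriminant_report <- function(x, ...) x$weights

#' Heatmap of per-pair discriminant weights
#'
#' 20 x 20 tile plot of [pair_discriminant_weights()]; the first amino acid
#' of each ordered pair on the y axis, the second on the x axis.
#'
#' @param object A `discriminant_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discriminant_report <- function(object, ...) {
  pw <- object$pair_weights
  pw$aa1 <- factor(pw$aa1, levels = rev(aa_alphabet))
  pw$aa2 <- factor(pw$aa2, levels = aa_alphabet)
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$aa2, y = .data$aa1,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Second amino acid", y = "First amino acid",
                  fill = "Weight") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Export discriminant tables as TSV
#'
#' Writes the 20 x 20 pair-weight matrix (with amino-acid row/column
#' headers), the per-lag tables of the top pairs, and optionally descriptor
#' occurrences.
#'
#' @param report A `discriminant_report`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
write_discriminant_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "pair_weights.tsv")
  utils::write.table(attr(report$pair_weights, "matrix"), p, sep = "\t",
                     quote = FALSE, col.names = NA)
  paths <- c(paths, p)
  lag_tab <- dplyr::bind_rows(report$per_lag, .id = "pair")
  p <- file.path(dir, "per_lag_weights.tsv")
  utils::write.table(lag_tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
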