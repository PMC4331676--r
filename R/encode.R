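#' Distance-transformation encoders
#'
#' The core encoding: a profile's L x 20 score matrix `S` (rows = positions,
#' columns = amino acids) is collapsed into a fixed-length vector of lagged
#' score products. For a lag `lg` and an ordered amino-acid pair `(a1, a2)`
#' the descriptor value is
#'
#'   sum_{j=1}^{L-lg} S\[j, a1\] * S\[j+lg, a2\]  /  (L - lg)
#'
#' which approximates the co-occurrence of `a1` and `a2` separated by `lg`
#' positions along the sequence. `encode_sdt()` keeps the 20 same-pair
#' descriptors per lag (length 20*LG), `encode_ddt()` the 380 ordered
#' different-pair descriptors (380*LG), and `encode_dt()` concatenates the
#' two blocks (400*LG, SDT first). No scaling or normalisation is applied
#' inside the encoders.
#'
#' @param profile A [pssm_profile()].
#' @param LG Maximum lag; the profile length must exceed `LG`.
#' @return A named numeric vector of class `feature_vector` with a
#'   [descriptor_schema()] attached as attribute `schema`.
#' @examples
#' p <- pssm_profile("toy", strrep("A", 10), matrix(1, 10, 20))
#' length(encode_dt(p, LG = 2))  # 800
#' @name dt_encoders
NULL

#' @rdname dt_encoders
#' @export
encode_sdt <- function(profile, LG) {
  encode_lagged(profile, LG, "sdt")
}

#' @rdname dt_encoders
#' @export
encode_ddt <- function(profile, LG) {
  encode_lagged(profile, LG, "ddt")
}

#' @rdname dt_encoders
#' @export
encode_dt <- function(profile, LG) {
  encode_lagged(profile, LG, "dt")
}

encode_lagged <- function(profile, LG, scheme) {
  stopifnot(is_pssm_profile(profile))
  schema <- descriptor_schema(scheme, LG)
  LG <- attr(schema, "LG")
  L <- profile_length(profile)
  if (L <= LG) {
    abort(sprintf(
      "Profile '%s' has length L = %d but the maximum lag LG = %d requires L > LG: the divisor (L - lg) must stay positive.",
      profile$id, L, LG))
  }
  S <- profile$scores
  # lag_products[a1, a2, lg] = sum_j S[j, a1] * S[j + lg, a2] / (L - lg)
  lag_products <- vapply(seq_len(LG), function(lg) {
    head_rows <- seq_len(L - lg)
    crossprod(S[head_rows, , drop = FALSE],
              S[head_rows + lg, , drop = FALSE]) / (L - lg)
  }, matrix(0, 20, 20))
  values <- lag_products[cbind(match(schema$aa1, aa_alphabet),
                               match(schema$aa2, aa_alphabet),
                               schema$lg)]
  new_feature_vector(values, schema)
}

new_feature_vector <- function(values, schema) {
  stopifnot(length(values) == nrow(schema), all(is.finite(values)))
  names(values) <- schema$name
  structure(values, schema = schema, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  s <- schema_of(x)
  cat(sprintf("<feature_vector> %s\n", describe_schema(s)))
  print(utils::head(unclass(x), 8))
  if (length(x) > 8) cat("...", length(x) - 8, "more coordinates\n")
  invisible(x)
}

#' Encode a set of profiles into a dataset tibble
#'
#' Applies one encoder to each profile and stacks the resulting vectors into
#' a samples-by-descriptors tibble with an `id` column (and a `label` column
#' when labels are supplied), ready to pipe into [svm_train()],
#' [grid_search()] or [jackknife()]. The descriptor schema travels with the
#' tibble as attribute `"schema"`.
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param scheme Encoding scheme name (see [descriptor_schema()]).
#' @param LG Maximum lag for the lagged schemes.
#' @param labels Optional vector over \{+1, -1\}, one per profile.
#' @return A tibble with one row per profile.
#' @examples
#' ps <- replicate(3, generate_profile(60, seed = 1), simplify = FALSE)
#' dim(encode_profiles(ps, "avepscore20"))
#' @export
encode_profiles <- function(profiles, scheme = "dt", LG = 5, labels = NULL) {
  stopifnot(length(profiles) >= 1L)
  encoder <- switch(scheme,
    sdt = function(p) encode_sdt(p, LG),
    ddt = function(p) encode_ddt(p, LG),
    dt = function(p) encode_dt(p, LG),
    avepscore20 = avepscore20,
    avepscore400 = avepscore400,
    pscore100 = pscore100,
    acc = function(p) acc_transform(p, LG),
    abort(sprintf(
      "Unknown scheme '%s'. Valid schemes: sdt, ddt, dt, avepscore20, avepscore400, pscore100, acc.",
      scheme)))
  vecs <- lapply(profiles, encoder)
  schema <- schema_of(vecs[[1]])
  mat <- do.call(rbind, lapply(vecs, unclass))
  ids <- vapply(seq_along(profiles), function(i) {
    id <- profiles[[i]]$id
    if (is.null(id) || !nzchar(id)) sprintf("seq%03d", i) else id
  }, character(1))
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(id = ids), out)
  if (!is.null(labels)) {
    check_labels(labels, length(profiles))
    out <- dplyr::bind_cols(tibble::tibble(id = ids, label = as.numeric(labels)),
                            tibble::as_tibble(as.data.frame(mat, check.names = FALSE)))
  }
  attr(out, "schema") <- schema
  out
}

check_labels <- function(labels, n) {
  if (length(labels) != n || !all(labels %in% c(-1, 1))) {
    abort("`labels` must have one entry in {+1, -1} per profile.")
  }
  invisible(labels)
}

# A dataset tibble's numeric feature matrix (drops id/label metadata columns).
feature_matrix <- function(data) {
  cols <- setdiff(names(data), c("id", "label"))
  m <- as.matrix(data[, cols, drop = FALSE])
  if (!is.numeric(m)) abort("Dataset feature columns must be numeric.")
  if (any(!is.finite(m))) abort("Dataset contains non-finite feature values.")
  m
}

#' Write an encoded dataset with its schema sidecar
#'
#' The dense table goes to `<path>.tsv` (id, label if present, then one
#' column per descriptor) and the schema to `<path>.schema.jsonl` via
#' [write_schema_sidecar()].
#'
#' @param data An encoded dataset tibble from [encode_profiles()].
#' @param path Output stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_dataset <- function(data, path) {
  tsv <- paste0(path, ".tsv")
  sidecar <- paste0(path, ".schema.jsonl")
  utils::write.table(data, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write_schema_sidecar(schema_of(data), sidecar)
  invisible(c(tsv, sidecar))
}

#' Read an encoded dataset written by [write_dataset()]
#'
#' @param path Stem used when writing.
#' @return A dataset tibble with the schema attribute restored.
#' @export
read_dataset <- function(path) {
  tsv <- paste0(path, ".tsv")
  sidecar <- paste0(path, ".schema.jsonl")
  tab <- tibble::as_tibble(utils::read.table(tsv, sep = "\t", header = TRUE,
                                             check.names = FALSE))
  lines <- readLines(sidecar)
  header <- jsonlite::fromJSON(lines[[1]])
  rows <- dplyr::bind_rows(lapply(lines[-1], function(l) {
    tibble::as_tibble(lapply(jsonlite::fromJSON(l), function(v) {
      if (is.null(v)) NA else v
    }))
  }))
  schema <- descriptor_schema(header$scheme,
                              LG = if (is.null(header$LG) || is.na(header$LG)) NULL else header$LG)
  if (!identical(schema$name, rows$name)) {
    abort("Schema sidecar does not match the canonical descriptor ordering.")
  }
  attr(tab, "schema") <- schema
  tab
}
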