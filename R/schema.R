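#' Descriptor schema for an encoding scheme
#'
#' Each coordinate of a feature vector is named by a descriptor. For the
#' distance-transformation schemes a descriptor is an ordered amino-acid pair
#' plus a lag: `(aa1, aa2, lg)`. Ordering is fixed and documented so that
#' feature analysis can map weights back to descriptors:
#' * `sdt`: the 20 * LG same-pair triples, amino-acid major (in
#'   [aa_alphabet] order), lag minor.
#' * `ddt`: the 380 * LG ordered different-pair triples, `(aa1, aa2)`
#'   lexicographic in [aa_alphabet] order, lag minor.
#' * `dt`: the 400 * LG concatenation, SDT block first.
#' Baseline schemes get analogous schemas with `lg = NA` where a lag does not
#' apply (`aa2` holds the residue class for `avepscore400`, the percentile
#' for `pscore100`).
#'
#' @param scheme One of `"sdt"`, `"ddt"`, `"dt"`, `"avepscore20"`,
#'   `"avepscore400"`, `"pscore100"`, `"acc"`.
#' @param LG Maximum lag (required for `sdt`, `ddt`, `dt`, `acc`).
#' @return A tibble with columns `index`, `name`, `aa1`, `aa2`, `lg` and
#'   attributes `scheme` and `LG`.
#' @examples
#' nrow(descriptor_schema("dt", LG = 5))  # 2000
#' @export
descriptor_schema <- function(scheme, LG = NULL) {
  scheme <- match.arg(scheme, c("sdt", "ddt", "dt", "avepscore20",
                                "avepscore400", "pscore100", "acc"))
  lag_schemes <- c("sdt", "ddt", "dt", "acc")
  if (scheme %in% lag_schemes) {
    if (is.null(LG) || length(LG) != 1L || is.na(LG) || LG < 1 ||
        LG != round(LG)) {
      abort(sprintf("Scheme '%s' requires an integer maximum lag LG >= 1.",
                    scheme))
    }
    LG <- as.integer(LG)
  } else {
    LG <- NA_integer_
  }
  tab <- switch(scheme,
    sdt = pair_lag_grid(same = TRUE, LG = LG),
    ddt = pair_lag_grid(same = FALSE, LG = LG),
    dt = dplyr::bind_rows(pair_lag_grid(TRUE, LG), pair_lag_grid(FALSE, LG)),
    acc = tidyr::crossing(aa1 = factor(aa_alphabet, aa_alphabet),
                          lg = seq_len(LG)) |>
      dplyr::mutate(aa1 = as.character(.data$aa1), aa2 = NA_character_),
    avepscore20 = tibble::tibble(aa1 = aa_alphabet, aa2 = NA_character_,
                                 lg = NA_integer_),
    avepscore400 = tidyr::crossing(aa1 = factor(aa_alphabet, aa_alphabet),
                                   aa2 = factor(aa_alphabet, aa_alphabet)) |>
      dplyr::mutate(dplyr::across(c("aa1", "aa2"), as.character),
                    lg = NA_integer_),
    pscore100 = tidyr::crossing(aa1 = factor(aa_alphabet, aa_alphabet),
                                pct = c(0, 25, 50, 75, 100)) |>
      dplyr::transmute(aa1 = as.character(.data$aa1),
                       aa2 = sprintf("p%d", .data$pct), lg = NA_integer_))
  tab <- tibble::as_tibble(tab)
  tab$index <- seq_len(nrow(tab))
  tab$name <- descriptor_names(tab, scheme)
  tab <- tab[, c("index", "name", "aa1", "aa2", "lg")]
  attr(tab, "scheme") <- scheme
  attr(tab, "LG") <- LG
  tab
}

pair_lag_grid <- function(same, LG) {
  grid <- tidyr::crossing(aa1 = factor(aa_alphabet, aa_alphabet),
                          aa2 = factor(aa_alphabet, aa_alphabet),
                          lg = seq_len(LG))
  grid <- dplyr::filter(grid, (as.character(.data$aa1) == as.character(.data$aa2)) == same)
  dplyr::mutate(grid, dplyr::across(c("aa1", "aa2"), as.character))
}

descriptor_names <- function(tab, scheme) {
  switch(scheme,
    avepscore20 = paste0("ave.", tab$aa1),
    avepscore400 = paste0("ave.", tab$aa1, ".", tab$aa2),
    pscore100 = paste0("pct.", tab$aa1, ".", tab$aa2),
    acc = sprintf("acc.%s.lg%d", tab$aa1, tab$lg),
    sprintf("%s.%s.lg%d", tab$aa1, tab$aa2, tab$lg))
}

schema_of <- function(x) attr(x, "schema", exact = TRUE)

same_schema <- function(a, b) {
  identical(attr(a, "scheme"), attr(b, "scheme")) &&
    identical(a$name, b$name)
}

describe_schema <- function(s) {
  sprintf("%s (LG=%s, %d descriptors)", attr(s, "scheme"),
          ifelse(is.na(attr(s, "LG")), "-", attr(s, "LG")), nrow(s))
}

#' Write a schema sidecar as JSON lines
#'
#' One JSON object per descriptor (`index`, `name`, `aa1`, `aa2`, `lg`),
#' preceded by a header object recording the scheme and LG, so external tools
#' can interpret the columns of an encoded dataset table.
#'
#' @param schema A [descriptor_schema()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema_sidecar <- function(schema, path) {
  header <- jsonlite::toJSON(
    list(scheme = attr(schema, "scheme"), LG = attr(schema, "LG"),
         n = nrow(schema)),
    auto_unbox = TRUE, na = "null")
  rows <- vapply(seq_len(nrow(schema)), function(i) {
    jsonlite::toJSON(as.list(schema[i, ]), auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
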