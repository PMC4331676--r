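#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the `-out_ascii_pssm` dialect: free-form header lines, a column-label
#' line carrying 40 amino-acid letters (20 for the log-odds block, 20 for the
#' weighted-percentage block), then one row per sequence position with the
#' position index, the residue letter, 20 integer log-odds scores, 20
#' percentage columns and two trailing per-position statistics. Only the
#' FIRST 20 (log-odds) columns are kept, reordered into canonical
#' [aa_alphabet] order; no rescaling or normalisation is applied.
#'
#' @param x PSSM text (string or lines) or a file path.
#' @param id Identifier for the resulting profile; defaults to the file base
#'   name when `x` is a path, `"pssm"` otherwise.
#' @return A [pssm_profile()].
#' @export
parse_ascii_pssm <- function(x, id = NULL) {
  if (is.null(id)) {
    id <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
              file.exists(x)) sub("\\.[^.]*$", "", basename(x)) else "pssm"
  }
  lines <- as_text_lines(x)

  label_idx <- NA_integer_
  labels <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) %in% c(20L, 40L) && all(toks %in% aa_alphabet)) {
      label_idx <- i
      labels <- toks[seq_len(20)]
      break
    }
  }
  if (is.na(label_idx)) {
    abort("No amino-acid column-label line found; not an ASCII PSSM.")
  }
  if (anyDuplicated(labels) || !setequal(labels, aa_alphabet)) {
    abort("Column-label line is not a permutation of the 20 amino acids.")
  }

  rows <- list()
  residues <- character(0)
  positions <- integer(0)
  for (i in seq((label_idx + 1L), length(lines))) {
    if (i > length(lines)) break
    line <- trimws(lines[[i]])
    if (!nzchar(line)) break
    toks <- strsplit(line, "\\s+")[[1]]
    # data rows start "<index> <residue-letter> <scores...>"
    if (!grepl("^[0-9]+$", toks[[1]])) break
    if (length(toks) < 2L || nchar(toks[[2]]) != 1L) break
    n_row <- length(rows) + 1L
    values <- toks[-(1:2)]
    if (length(values) < 20L) {
      abort(sprintf("PSSM row %d has %d score fields; 20 log-odds columns expected.",
                    n_row, length(values)))
    }
    scores <- suppressWarnings(as.numeric(values[seq_len(20)]))
    if (any(is.na(scores))) {
      bad <- values[seq_len(20)][is.na(scores)][[1]]
      abort(sprintf("PSSM row %d contains a non-numeric score cell: '%s'.",
                    n_row, bad))
    }
    rows[[n_row]] <- scores
    residues[n_row] <- toupper(toks[[2]])
    positions[n_row] <- as.integer(toks[[1]])
  }
  if (length(rows) == 0L) {
    abort("ASCII PSSM contains no score rows.")
  }
  if (!identical(positions, seq_along(positions))) {
    abort(sprintf(
      "PSSM position indices are not consecutive from 1: parsed %d rows, last index %d.",
      length(positions), positions[length(positions)]))
  }
  scores <- do.call(rbind, rows)
  pssm_profile(id, paste(residues, collapse = ""), scores, alphabet = labels)
}

#' Write a profile in the ASCII PSSM dialect
#'
#' Emits text that [parse_ascii_pssm()] reads back exactly: header, 40-letter
#' column-label line, one row per position with the 20 log-odds scores
#' repeated into the percentage block, and two zero trailing statistics.
#' Real-valued synthetic scores are written as-is, so write/parse round-trips
#' scores and residues exactly.
#'
#' @param profile A [pssm_profile()].
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character lines, invisibly when written to `path`.
#' @export
write_ascii_pssm <- function(profile, path = NULL) {
  stopifnot(is_pssm_profile(profile))
  S <- profile$scores
  res <- strsplit(profile$residues, "")[[1]]
  header <- c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(rep(sprintf("%3s", aa_alphabet), 2), collapse = " ")))
  fmt_num <- function(v) {
    out <- ifelse(v == round(v), sprintf("%3d", as.integer(round(v))),
                  sprintf("%.6g", v))
    paste(out, collapse = " ")
  }
  body <- vapply(seq_len(nrow(S)), function(i) {
    sprintf("%5d %s %s %s  0.00 0.00", i, res[i], fmt_num(S[i, ]), fmt_num(S[i, ]))
  }, character(1))
  lines <- c(header, body, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read a directory of per-sequence profiles
#'
#' Expects one `<id>.pssm` file per FASTA record. When `fasta` is given, the
#' returned profiles follow the FASTA record order and a missing profile for
#' any record is an error listing the ids.
#'
#' @param dir Directory containing `*.pssm` files.
#' @param fasta Optional FASTA path/text used to fix the expected ids and
#'   order.
#' @return A list of [pssm_profile()] objects.
#' @export
read_profile_dir <- function(dir, fasta = NULL) {
  if (!dir.exists(dir)) abort(sprintf("Profile directory '%s' not found.", dir))
  if (!is.null(fasta)) {
    ids <- vapply(read_fasta(fasta), `[[`, character(1), "id")
    paths <- file.path(dir, paste0(ids, ".pssm"))
    missing <- ids[!file.exists(paths)]
    if (length(missing) > 0L) {
      abort(sprintf("Missing profile file(s) for: %s.",
                    paste(missing, collapse = ", ")))
    }
  } else {
    paths <- sort(list.files(dir, pattern = "\\.pssm$", full.names = TRUE))
    if (length(paths) == 0L) {
      abort(sprintf("No .pssm files found in '%s'.", dir))
    }
  }
  lapply(paths, parse_ascii_pssm)
}
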