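#' Read protein sequences from FASTA text or a file
#'
#' Parses multi-record FASTA (wrapped or unwrapped). Records keep their input
#' order; whitespace and line wrapping are normalised away. Any residue
#' outside the 20 canonical one-letter codes (including the ambiguity code
#' `X`) is an error naming the record and the offending character.
#'
#' @param x FASTA text (a single string or character vector of lines) or the
#'   path of a FASTA file.
#' @return A list of sequences, each a list with `id` and `residues`.
#' @examples
#' read_fasta(">p1\nMKR\n")
#' @export
read_fasta <- function(x) {
  lines <- as_text_lines(x)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort("Empty FASTA input.")
  }
  if (!startsWith(lines[[1]], ">")) {
    abort("FASTA input must start with a '>' header line.")
  }
  header_idx <- which(startsWith(lines, ">"))
  starts <- header_idx + 1L
  ends <- c(header_idx[-1] - 1L, length(lines))
  seqs <- purrr::map2(seq_along(header_idx), seq_along(header_idx), function(i, ...) {
    id <- sub("^>\\s*", "", lines[[header_idx[i]]])
    id <- strsplit(id, "\\s+")[[1]][1]
    if (is.na(id) || !nzchar(id)) {
      abort(sprintf("FASTA record %d has an empty identifier.", i))
    }
    body <- if (starts[i] > ends[i]) character(0) else lines[starts[i]:ends[i]]
    residues <- toupper(gsub("\\s", "", paste(body, collapse = "")))
    if (!nzchar(residues)) {
      abort(sprintf("FASTA record '%s' has an empty sequence.", id))
    }
    validate_residues(residues, id)
    list(id = id, residues = residues)
  })
  seqs
}

#' Write sequences as FASTA text
#'
#' @param seqs List of sequences (`id`, `residues`), as from [read_fasta()],
#'   or a list of [pssm_profile()] objects.
#' @param path Optional file path; when `NULL` the FASTA text is returned.
#' @param width Line-wrap width for residues.
#' @return The FASTA lines, invisibly when written to `path`.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60) {
  lines <- unlist(lapply(seqs, function(s) {
    res <- s$residues
    chunks <- substring(res, seq(1, nchar(res), width),
                        pmin(seq(1, nchar(res), width) + width - 1, nchar(res)))
    c(paste0(">", s$id), chunks)
  }))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# Accept a path, a single multi-line string, or a vector of lines.
as_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}
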