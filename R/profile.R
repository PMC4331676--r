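#' The canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in PSI-BLAST header order
#' (A R N D C Q E G H I L K M F P S T W Y V). Every PSSM score matrix in this
#' package has its 20 columns in this order, and every descriptor schema
#' enumerates pairs in it.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM profile
#'
#' A PSSM profile couples a protein sequence with its L x 20 matrix of
#' position-specific log-odds scores, one row per residue and one column per
#' canonical amino acid (in [aa_alphabet] order). Scores are stored as reals
#' even though PSI-BLAST prints integers, so synthetic profiles may carry
#' real-valued scores.
#'
#' @param id Sequence identifier (single string).
#' @param residues Residue string over the 20 canonical one-letter codes.
#'   Ambiguity codes such as `X` are rejected.
#' @param scores Numeric matrix with `nchar(residues)` rows and 20 columns.
#'   Columns are taken to be in [aa_alphabet] order unless `alphabet` says
#'   otherwise, in which case they are reordered.
#' @param alphabet Column order of `scores`; a permutation of [aa_alphabet].
#'
#' @return An object of class `pssm_profile`: a list with elements `id`,
#'   `residues` and `scores` (columns canonically ordered and named).
#' @examples
#' p <- pssm_profile("toy", "MKR", matrix(0, 3, 20))
#' dim(p$scores)
#' @export
pssm_profile <- function(id, residues, scores, alphabet = aa_alphabet) {
  stopifnot(is.character(id), length(id) == 1L)
  validate_residues(residues, id)
  scores <- as.matrix(scores)
  if (!is.numeric(scores)) {
    abort("`scores` must be a numeric matrix.")
  }
  if (any(!is.finite(scores))) {
    abort(sprintf("Profile '%s' contains non-finite scores.", id))
  }
  if (ncol(scores) != 20L) {
    abort(sprintf("Profile '%s': expected 20 score columns, found %d.",
                  id, ncol(scores)))
  }
  if (nrow(scores) != nchar(residues)) {
    abort(sprintf(
      "Profile '%s': %d score rows but %d residues; they must match.",
      id, nrow(scores), nchar(residues)))
  }
  if (!setequal(alphabet, aa_alphabet) || length(alphabet) != 20L) {
    abort("`alphabet` must be a permutation of the 20 canonical amino acids.")
  }
  scores <- scores[, match(aa_alphabet, alphabet), drop = FALSE]
  dimnames(scores) <- list(NULL, aa_alphabet)
  structure(list(id = id, residues = residues, scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s  (L = %d)\n", x$id, nrow(x$scores)))
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(" residues:", res, "\n")
  cat(" score range: [", min(x$scores), ", ", max(x$scores), "]\n", sep = "")
  invisible(x)
}

profile_length <- function(profile) nrow(profile$scores)

is_pssm_profile <- function(x) inherits(x, "pssm_profile")

# Reject anything outside the 20 canonical codes: ambiguity codes make the
# column products in the encoders ill-defined, mirroring the curation rule
# that drops sequences containing 'X'.
validate_residues <- function(residues, id = "<sequence>") {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (nchar(residues) < 1L) {
    abort(sprintf("Sequence '%s' is empty.", id))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), aa_alphabet)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Sequence '%s' contains illegal residue character(s): %s. Only the 20 canonical amino-acid codes are accepted.",
      id, paste(sQuote(bad), collapse = ", ")))
  }
  invisible(residues)
}

#' Validate sequences against the curation length rule
#'
#' Benchmark curation for this classifier drops sequences shorter than a
#' minimum length (50 residues in the original benchmark). This check is an
#' optional dataset-curation filter, not an I/O invariant: the parsers accept
#' any length >= 1.
#'
#' @param seqs A list of sequences as returned by [read_fasta()].
#' @param min_length Minimum accepted length (default 50).
#' @return `seqs`, with sequences shorter than `min_length` removed.
#' @export
filter_min_length <- function(seqs, min_length = 50) {
  keep <- vapply(seqs, function(s) nchar(s$residues) >= min_length, logical(1))
  seqs[keep]
}
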