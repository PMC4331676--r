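#' Generate a PSSM profile with PSI-BLAST
#'
#' Convenience wrapper that writes the query to a temporary FASTA, runs
#' `psiblast` against a formatted protein database with the stated number of
#' iterations and E-value cutoff (defaults: 3 iterations, E-value 0.001), and
#' parses the emitted ASCII PSSM. Everything else in the package works from
#' pre-computed profiles; this operation is never required.
#'
#' @param seq A sequence (list with `id`, `residues`) or a single FASTA
#'   record's text.
#' @param db_path Path of a formatted BLAST protein database.
#' @param iterations Number of PSI-BLAST iterations.
#' @param evalue_cutoff Inclusion E-value threshold.
#' @param psiblast Path of the `psiblast` executable.
#' @return A [pssm_profile()].
#' @export
run_psiblast <- function(seq, db_path, iterations = 3, evalue_cutoff = 0.001,
                         psiblast = "psiblast") {
  if (is.character(seq)) seq <- read_fasta(seq)[[1]]
  validate_residues(seq$residues, seq$id)
  if (Sys.which(psiblast) == "" && !file.exists(psiblast)) {
    abort(paste0(
      "PSI-BLAST executable '", psiblast, "' not found. Install the NCBI ",
      "BLAST+ suite (which provides `psiblast`) or pass its location via ",
      "`psiblast=`; alternatively supply pre-computed ASCII PSSM profiles."))
  }
  qfile <- tempfile("query_", fileext = ".fasta")
  pfile <- tempfile("profile_", fileext = ".pssm")
  on.exit(unlink(c(qfile, pfile)), add = TRUE)
  write_fasta(list(seq), qfile)
  args <- c("-query", qfile,
            "-db", db_path,
            "-num_iterations", format(iterations),
            "-evalue", format(evalue_cutoff),
            "-out_ascii_pssm", pfile,
            "-out", "/dev/null")
  status <- tryCatch(
    system2(psiblast, args, stdout = TRUE, stderr = TRUE),
    warning = function(w) w)
  code <- attr(status, "status")
  if (inherits(status, "warning") || (!is.null(code) && code != 0)) {
    abort(sprintf("psiblast exited with an error for '%s':\n%s", seq$id,
                  paste(as.character(status), collapse = "\n")))
  }
  if (!file.exists(pfile) || file.size(pfile) == 0) {
    abort(sprintf(
      paste0("psiblast produced no PSSM for '%s' (likely no database hits). ",
             "Consider a larger database; a profile cannot be built from a ",
             "single sequence alone."), seq$id))
  }
  parse_ascii_pssm(pfile, id = seq$id)
}
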