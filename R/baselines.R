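#' Comparison PSSM encoders
#'
#' Four established PSSM summary encodings used as comparison baselines for
#' the distance-transformation schemes. Each is frozen to one precise
#' definition here (stated per function) and labelled by scheme name in its
#' schema, since the originating descriptions are one-line summaries.
#'
#' @param profile A [pssm_profile()].
#' @return A `feature_vector` (see [encode_dt()]).
#' @name baseline_encoders
NULL

#' @describeIn baseline_encoders 20 values: the mean of each score column
#'   over all positions.
#' @export
avepscore20 <- function(profile) {
  stopifnot(is_pssm_profile(profile))
  new_feature_vector(colMeans(profile$scores),
                     descriptor_schema("avepscore20"))
}

#' @describeIn baseline_encoders 400 values indexed (residue class r, column
#'   a): the mean of column a over exactly the positions whose sequence
#'   residue is r, and 0 when r never occurs in the sequence.
#' @export
avepscore400 <- function(profile) {
  stopifnot(is_pssm_profile(profile))
  res <- factor(strsplit(profile$residues, "")[[1]], levels = aa_alphabet)
  by_class <- rowsum(profile$scores, res)            # sums per residue class
  counts <- as.integer(table(res))
  means <- matrix(0, 20, 20, dimnames = list(aa_alphabet, aa_alphabet))
  present <- counts > 0
  means[present, ] <- by_class[rownames(by_class) %in% aa_alphabet[present], ,
                               drop = FALSE] / counts[present]
  schema <- descriptor_schema("avepscore400")
  new_feature_vector(means[cbind(match(schema$aa1, aa_alphabet),
                                 match(schema$aa2, aa_alphabet))], schema)
}

#' @describeIn baseline_encoders 100 values: per score column, the empirical
#'   percentiles at 0/25/50/75/100% by linear interpolation between order
#'   statistics (`stats::quantile()` type 7).
#' @export
pscore100 <- function(profile) {
  stopifnot(is_pssm_profile(profile))
  q <- apply(profile$scores, 2, quantile, probs = c(0, .25, .5, .75, 1),
             names = FALSE)                           # 5 x 20
  new_feature_vector(as.vector(q), descriptor_schema("pscore100"))
}

#' @describeIn baseline_encoders 20*LG values: the lagged auto-covariance of
#'   each score column, `sum_j (S[j,a] - m_a)(S[j+lg,a] - m_a) / (L - lg)`
#'   with `m_a` the full-column mean. Covariance, not Pearson correlation;
#'   divisor `L - lg` to parallel the distance-transformation schemes.
#' @param LG Maximum lag (`acc_transform` only); profile length must exceed it.
#' @export
acc_transform <- function(profile, LG) {
  stopifnot(is_pssm_profile(profile))
  schema <- descriptor_schema("acc", LG)
  LG <- attr(schema, "LG")
  L <- profile_length(profile)
  if (L <= LG) {
    abort(sprintf("Profile '%s' has length L = %d but LG = %d requires L > LG.",
                  profile$id, L, LG))
  }
  centred <- sweep(profile$scores, 2, colMeans(profile$scores))
  per_lag <- vapply(seq_len(LG), function(lg) {
    head_rows <- seq_len(L - lg)
    colSums(centred[head_rows, , drop = FALSE] *
            centred[head_rows + lg, , drop = FALSE]) / (L - lg)
  }, numeric(20))                                     # 20 x LG
  values <- per_lag[cbind(match(schema$aa1, aa_alphabet), schema$lg)]
  new_feature_vector(values, schema)
}
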