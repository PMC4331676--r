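#' Generate one synthetic PSSM profile
#'
#' Residues are drawn uniformly over the 20 canonical amino acids and scores
#' independently from a discretised normal background (`round(N(mean, sd))`),
#' mimicking the integer log-odds range of real profiles (roughly -6..6 at
#' the default `sd = 2`). Deterministic given `seed`. The generator does not
#' emulate alignment pseudocounts or per-column information content — scores
#' are i.i.d. noise unless a signal is planted by [generate_dataset()].
#'
#' @param length Sequence length (>= 1).
#' @param mean,sd Background score distribution parameters.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param id Profile identifier.
#' @return A [pssm_profile()].
#' @export
generate_profile <- function(length, mean = 0, sd = 2, seed = NULL,
                             id = "synthetic") {
  if (length < 1) abort("`length` must be >= 1.")
  gen <- function() {
    residues <- paste(sample(aa_alphabet, length, replace = TRUE),
                      collapse = "")
    scores <- matrix(round(stats::rnorm(length * 20, mean, sd)), length, 20)
    pssm_profile(id, residues, scores)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Plant specification for synthetic datasets
#'
#' Describes the signal planted into positive-class profiles: a set of
#' `(aa1, aa2, lg)` descriptor triples, the score boost added where they are
#' planted, and the fraction of eligible positions receiving a plant.
#'
#' @param pairs Data frame with columns `aa1`, `aa2`, `lg` (lags >= 1). The
#'   default plants (R,R) at lag 4 and (A,R) at lag 5 — arginine-centred
#'   pairings of the kind that distinguish DNA-binding proteins.
#' @param effect_size Non-negative score boost added at planted positions;
#'   the default 5 is 2.5 background standard deviations.
#' @param density Fraction in (0, 1] of eligible positions planted.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(pairs = tibble::tibble(aa1 = c("R", "A"),
                                              aa2 = c("R", "R"),
                                              lg = c(4L, 5L)),
                       effect_size = 5, density = 0.25) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("aa1", "aa2", "lg") %in% names(pairs)),
            all(pairs$aa1 %in% aa_alphabet), all(pairs$aa2 %in% aa_alphabet))
  if (any(pairs$lg < 1) || any(pairs$lg != round(pairs$lg))) {
    abort("Planted lags must be integers >= 1.")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (density <= 0 || density > 1) abort("`density` must lie in (0, 1].")
  structure(list(pairs = pairs, effect_size = effect_size, density = density),
            class = "plant_spec")
}

#' Generate a labeled synthetic dataset of PSSM profiles
#'
#' Negatives are pure background ([generate_profile()]). Positives are
#' background plus a planted pair/lag signal: for each planted triple
#' `(aa1, aa2, lg)`, a `density`-controlled subset of eligible start
#' positions `j` receives simultaneous boosts of `+effect_size` to column
#' `aa1` at row `j` and column `aa2` at row `j + lg`, and the residue
#' letters at `j` and `j + lg` are set to `aa1` and `aa2`. Scores and
#' letters are planted coherently so that profile-based encoders and the
#' sequence-based occurrence locator see the same signal; planted SDT/DDT
#' coordinates therefore have elevated expectation in positives. Fully
#' deterministic given `seed`.
#'
#' @param n_pos,n_neg Class sizes (>= 1). Defaults give the n = 60 study
#'   size used throughout the package's validation.
#' @param length_range Inclusive (min, max) sequence lengths; the minimum
#'   must exceed the largest planted lag.
#' @param plant A [plant_spec()].
#' @param mean,sd Background score distribution.
#' @param seed Integer seed.
#' @return A list with `profiles` (positives first), `labels` (+1/-1) and
#'   `ids`.
#' @examples
#' d <- generate_dataset(n_pos = 3, n_neg = 3, seed = 7)
#' d$labels
#' @export
generate_dataset <- function(n_pos = 30, n_neg = 30, length_range = c(60, 100),
                             plant = plant_spec(), mean = 0, sd = 2,
                             seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2L)
  if (length_range[[1]] <= max(plant$pairs$lg)) {
    abort(sprintf(
      "Minimum length %d must exceed the largest planted lag %d.",
      length_range[[1]], max(plant$pairs$lg)))
  }
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    lens <- sample(seq(length_range[[1]], length_range[[2]]), n, replace = TRUE)
    labels <- c(rep(1, n_pos), rep(-1, n_neg))
    ids <- sprintf("%s%03d", ifelse(labels == 1, "pos", "neg"),
                   c(seq_len(n_pos), seq_len(n_neg)))
    profiles <- lapply(seq_len(n), function(i) {
      p <- generate_profile(lens[[i]], mean = mean, sd = sd, id = ids[[i]])
      if (labels[[i]] == 1) p <- plant_signal(p, plant)
      p
    })
    list(profiles = profiles, labels = labels, ids = ids)
  })
}

# Boost scores and set residue letters at a density-controlled subset of
# eligible start positions for every planted triple. Uses the current RNG
# state (generate_dataset seeds it).
plant_signal <- function(profile, plant) {
  if (plant$effect_size == 0) return(profile)
  chars <- strsplit(profile$residues, "")[[1]]
  S <- profile$scores
  L <- length(chars)
  for (r in seq_len(nrow(plant$pairs))) {
    aa1 <- plant$pairs$aa1[[r]]
    aa2 <- plant$pairs$aa2[[r]]
    lg <- plant$pairs$lg[[r]]
    eligible <- seq_len(L - lg)
    k <- max(1L, round(plant$density * length(eligible)))
    at <- sort(sample(eligible, k))
    S[at, aa1] <- S[at, aa1] + plant$effect_size
    S[at + lg, aa2] <- S[at + lg, aa2] + plant$effect_size
    chars[at] <- aa1
    chars[at + lg] <- aa2
  }
  pssm_profile(profile$id, paste(chars, collapse = ""), S)
}

#' Write a synthetic dataset as FASTA plus ASCII PSSM files
#'
#' Emits `sequences.fasta`, one `<id>.pssm` per profile in the ASCII PSSM
#' dialect, and `labels.tsv`, so synthetic data can exercise the real
#' parsers end-to-end.
#'
#' @param dataset A list from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$profiles, file.path(dir, "sequences.fasta"))
  for (p in dataset$profiles) {
    write_ascii_pssm(p, file.path(dir, paste0(p$id, ".pssm")))
  }
  utils::write.table(
    data.frame(id = dataset$ids, label = dataset$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
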