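# Independent naive-loop oracles and fixture builders. The oracles iterate
# the defining sums position by position and never share code with the
# package's vectorized encoders.

AA <- pssmdt::aa_alphabet

random_profile <- function(L, seed, real_valued = FALSE) {
  withr::with_seed(seed, {
    res <- paste(sample(AA, L, replace = TRUE), collapse = "")
    sc <- if (real_valued) matrix(rnorm(L * 20, 0, 2), L, 20) else
      matrix(round(rnorm(L * 20, 0, 2)), L, 20)
    pssm_profile(sprintf("rnd%d", seed), res, sc)
  })
}

# profile with chosen columns set and everything else zero
column_profile <- function(columns, L) {
  S <- matrix(0, L, 20, dimnames = list(NULL, AA))
  for (a in names(columns)) S[, a] <- columns[[a]]
  pssm_profile("cols", strrep("G", L), S)
}

naive_sdt <- function(profile, LG) {
  S <- profile$scores; L <- nrow(S)
  out <- numeric(0)
  for (a in AA) for (lg in seq_len(LG)) {
    s <- 0
    for (j in seq_len(L - lg)) s <- s + S[j, a] * S[j + lg, a]
    out <- c(out, s / (L - lg))
  }
  unname(out)
}

naive_ddt <- function(profile, LG) {
  S <- profile$scores; L <- nrow(S)
  out <- numeric(0)
  for (a1 in AA) for (a2 in AA) {
    if (a1 == a2) next
    for (lg in seq_len(LG)) {
      s <- 0
      for (j in seq_len(L - lg)) s <- s + S[j, a1] * S[j + lg, a2]
      out <- c(out, s / (L - lg))
    }
  }
  unname(out)
}

naive_ave20 <- function(profile) {
  vapply(AA, function(a) mean(profile$scores[, a]), numeric(1))
}

naive_ave400 <- function(profile) {
  chars <- strsplit(profile$residues, "")[[1]]
  out <- numeric(0)
  for (r in AA) for (a in AA) {
    rows <- which(chars == r)
    out <- c(out, if (length(rows) == 0) 0 else mean(profile$scores[rows, a]))
  }
  unname(out)
}

naive_pscore100 <- function(profile) {
  out <- numeric(0)
  for (a in AA) {
    v <- sort(profile$scores[, a])
    n <- length(v)
    for (p in c(0, .25, .5, .75, 1)) {
      h <- (n - 1) * p            # linear interpolation between order stats
      lo <- floor(h) + 1
      out <- c(out, v[lo] + (h - floor(h)) * (v[min(lo + 1, n)] - v[lo]))
    }
  }
  unname(out)
}

naive_acc <- function(profile, LG) {
  S <- profile$scores; L <- nrow(S)
  out <- numeric(0)
  for (a in AA) {
    m <- mean(S[, a])
    for (lg in seq_len(LG)) {
      s <- 0
      for (j in seq_len(L - lg)) s <- s + (S[j, a] - m) * (S[j + lg, a] - m)
      out <- c(out, s / (L - lg))
    }
  }
  unname(out)
}

# brute-force AUC over all positive-negative pairs, ties credited 0.5
naive_auc <- function(values, labels) {
  pos <- values[labels == 1]; neg <- values[labels == -1]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# ASCII PSSM text in the psiblast -out_ascii_pssm layout, built by hand
ascii_pssm_text <- function(scores, residues, labels = AA) {
  stopifnot(ncol(scores) == 20, nrow(scores) == nchar(residues))
  chars <- strsplit(residues, "")[[1]]
  c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(rep(labels, 2), collapse = "  ")),
    vapply(seq_len(nrow(scores)), function(i) {
      paste0(sprintf("%5d %s ", i, chars[i]),
             paste(sprintf("%3d", scores[i, ]), collapse = " "), " ",
             paste(rep(" 10", 20), collapse = ""), "  0.36 0.09")
    }, character(1)),
    "", "                      K         Lambda", "Standard Ungapped    0.1337     0.3157")
}

toy_dataset_tibble <- function(x, y, ids = NULL) {
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(x)))
  out <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(id = ids, label = y), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
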