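fake_model <- function(dual, index, sv, schema = NULL) {
  structure(list(support_vectors = sv, dual_coefficients = dual,
                 support_index = index, bias = 0, C = 1, gamma = 1,
                 scaling = NULL, schema = schema,
                 n_train = max(index)), class = "dt_svm")
}

test_that("discriminant weights are the A'M read-out", {
  # identity feature matrix: W reproduces A
  M <- diag(2)
  colnames(M) <- c("f1", "f2")
  data <- toy_dataset_tibble(M, c(1, -1))
  model <- fake_model(c(1, -1), 1:2, M)
  expect_equal(discriminant_weights(model, data)$weight, c(1, -1))

  # hand product: A = (2, 1, -3), M rows (1,0), (0,1), (1,1)
  M2 <- rbind(c(1, 0), c(0, 1), c(1, 1))
  colnames(M2) <- c("f1", "f2")
  data2 <- toy_dataset_tibble(M2, c(1, 1, -1))
  model2 <- fake_model(c(2, 1, -3), 1:3, M2)
  expect_equal(discriminant_weights(model2, data2)$weight, c(-1, -2))
})

test_that("discriminant weights are linear in the dual weights", {
  withr::with_seed(8, {
    M <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
    data <- toy_dataset_tibble(M, c(1, 1, -1, -1))
    A <- c(0.5, -0.2, 0.9, -1.2)
    w1 <- discriminant_weights(fake_model(A, 1:4, M), data)$weight
    w3 <- discriminant_weights(fake_model(3 * A, 1:4, M), data)$weight
    expect_equal(w3, 3 * w1)
  })
})

test_that("pair weights square-and-sum only positive descriptor weights", {
  schema <- descriptor_schema("dt", LG = 5)
  W <- numeric(nrow(schema))
  rr <- schema$aa1 == "R" & schema$aa2 == "R"
  W[rr] <- c(0.3, -0.2, 0.4, 0, 0)
  weights <- dplyr::mutate(schema, weight = W)
  pw <- pair_discriminant_weights(weights)
  expect_equal(pw$weight[pw$aa1 == "R" & pw$aa2 == "R"], 0.3^2 + 0.4^2)
  expect_equal(pw$aa1[1], "R")           # ranked first
  mat <- attr(pw, "matrix")
  expect_equal(dim(mat), c(20, 20))
  expect_equal(mat["R", "R"], 0.25)
  expect_true(all(mat >= 0))

  all_neg <- dplyr::mutate(schema, weight = -abs(rnorm(nrow(schema))))
  expect_true(all(pair_discriminant_weights(all_neg)$weight == 0))
})

test_that("pair weights partition the positive-part quadratic mass", {
  withr::with_seed(17, {
    schema <- descriptor_schema("dt", LG = 3)
    weights <- dplyr::mutate(schema, weight = rnorm(nrow(schema)))
    pw <- pair_discriminant_weights(weights)
    expect_equal(sum(pw$weight),
                 sum(weights$weight[weights$weight > 0]^2))
    expect_equal(nrow(pw), 400)
  })
})

test_that("per-lag weights return signed coordinates in lag order", {
  schema <- descriptor_schema("dt", LG = 4)
  weights <- dplyr::mutate(schema, weight = as.numeric(seq_len(nrow(schema))))
  pl <- per_lag_weights(weights, c("A", "R"))
  expect_equal(pl$lg, 1:4)
  expect_equal(nrow(pl), 4)
  # consistency with the pair quadratic sum
  pw <- pair_discriminant_weights(weights)
  expect_equal(sum(pl$weight[pl$weight > 0]^2),
               pw$weight[pw$aa1 == "A" & pw$aa2 == "R"])
  expect_error(per_lag_weights(weights, c("A", "Z")), "canonical")
  expect_error(per_lag_weights(weights, c("B")), "canonical")
})

test_that("descriptor occurrences are exhaustive 1-based position pairs", {
  expect_equal(locate_descriptor_occurrences("ARPR", c("A", "R"), 1),
               tibble::tibble(pos1 = 1L, pos2 = 2L))
  expect_equal(locate_descriptor_occurrences("ARPR", c("R", "R"), 2),
               tibble::tibble(pos1 = 2L, pos2 = 4L))
  expect_equal(locate_descriptor_occurrences("ARPR", c("P", "R"), 1),
               tibble::tibble(pos1 = 3L, pos2 = 4L))
  expect_equal(locate_descriptor_occurrences("RRRR", c("R", "R"), 1)$pos1,
               1:3)
  expect_equal(nrow(locate_descriptor_occurrences("ARPR", c("W", "W"), 1)), 0)
  expect_error(locate_descriptor_occurrences("ARXR", c("A", "R"), 1), "'X'")
  expect_error(locate_descriptor_occurrences("ARPR", c("A", "R"), 4),
               "smaller than the sequence length")
})

test_that("occurrence scan matches a brute-force oracle on random sequences", {
  withr::with_seed(29, {
    for (i in 1:5) {
      res <- paste(sample(AA, 30, replace = TRUE), collapse = "")
      pair <- sample(AA, 2, replace = TRUE)
      lg <- sample(1:4, 1)
      got <- locate_descriptor_occurrences(res, pair, lg)
      chars <- strsplit(res, "")[[1]]
      expected <- Filter(function(j) chars[j] == pair[1] &&
                           chars[j + lg] == pair[2], 1:(30 - lg))
      expect_equal(got$pos1, as.integer(expected))
    }
  })
})

test_that("planted descriptors dominate the discriminant read-out", {
  d <- generate_dataset(n_pos = 12, n_neg = 12, seed = 71)
  enc <- encode_profiles(d$profiles, "dt", LG = 5, labels = d$labels)
  model <- svm_train(enc, C = 8)
  rep <- discriminant_report(model, enc)
  planted <- c("R-R", "A-R")
  expect_true(all(planted %in% rep$ranked_pairs[1:4]))
  # planted coordinates carry larger mean magnitude than background
  w <- rep$weights
  is_planted <- (w$aa1 == "R" & w$aa2 == "R" & w$lg == 4) |
    (w$aa1 == "A" & w$aa2 == "R" & w$lg == 5)
  expect_gt(mean(abs(w$weight[is_planted])), mean(abs(w$weight[!is_planted])))
  # per-lag profile of (R,R) peaks at the planted lag 4
  pl <- per_lag_weights(w, c("R", "R"))
  expect_equal(pl$lg[which.max(pl$weight)], 4L)
  expect_s3_class(autoplot(rep), "ggplot")
  dir <- withr::local_tempdir()
  paths <- write_discriminant_tables(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("pair_weights.tsv",
                                               "per_lag_weights.tsv")))))
})
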