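# Gaussian blobs: a small two-class dataset with controllable separation.
blob_data <- function(n_per = 8, sep = 3, seed = 1, d = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * d, sep / 2), ncol = d),
               matrix(rnorm(n_per * d, -sep / 2), ncol = d))
    colnames(x) <- sprintf("f%d", seq_len(d))
    toy_dataset_tibble(x, c(rep(1, n_per), rep(-1, n_per)))
  })
}

test_that("well-separated clouds train to perfect resubstitution accuracy", {
  data <- blob_data(sep = 8, seed = 2)
  model <- svm_train(data, C = 10, gamma = 0.5)
  pred <- predict(model, data)
  expect_equal(pred$label, data$label)
})

test_that("training points satisfy the soft-margin constraints", {
  data <- blob_data(sep = 2, seed = 3)
  C <- 2
  model <- svm_train(data, C = C, gamma = 0.5)
  f <- predict(model, data)$decision_value
  slack <- pmax(0, 1 - data$label * f)          # recovered xi_i
  expect_true(all(slack >= 0))
  expect_true(all(data$label * f >= 1 - slack - 1e-8))
  # dual box constraint 0 < |alpha_i y_i| <= C for every support vector
  expect_true(all(abs(model$dual_coefficients) <= C + 1e-8))
  expect_true(all(abs(model$dual_coefficients) > 0))
})

test_that("decision values agree with a direct dual QP solve", {
  skip_if_not_installed("kernlab")
  for (seed in c(5, 9)) {
    data <- blob_data(n_per = 8, sep = 3, seed = seed)   # n = 16 <= 20
    C <- 1; gamma <- 0.5
    model <- svm_train(data, C = C, gamma = gamma, tolerance = 1e-9)
    x <- as.matrix(data[, c("f1", "f2")])
    y <- data$label
    K <- exp(-gamma * as.matrix(dist(x))^2)
    sol <- kernlab::ipop(c = matrix(-1, nrow(x), 1), H = (y %o% y) * K,
                         A = t(y), b = 0, r = 0,
                         l = matrix(0, nrow(x), 1),
                         u = matrix(C, nrow(x), 1), sigf = 12, maxiter = 400)
    alpha <- kernlab::primal(sol)
    free <- alpha > 1e-6 & alpha < C - 1e-6
    b <- mean(y[free] - drop(K[free, , drop = FALSE] %*% (alpha * y)))
    f_qp <- unname(drop(K %*% (alpha * y)) + b)
    f_pkg <- predict(model, data)$decision_value
    expect_equal(f_pkg, f_qp, tolerance = 1e-6)
  }
})

test_that("kernel expansion reproduces closed-form two-support-vector arithmetic", {
  s <- rbind(c(0, 0), c(3, 0))
  colnames(s) <- c("f1", "f2")
  model <- structure(list(support_vectors = s,
                          dual_coefficients = c(0.7, -0.4),
                          support_index = 1:2, bias = 0.1,
                          C = 1, gamma = 0.25, scaling = NULL,
                          schema = NULL, n_train = 2), class = "dt_svm")
  x <- c(1, 2)
  f <- predict(model, toy_dataset_tibble(matrix(x, 1,
                  dimnames = list(NULL, c("f1", "f2"))), 1))$decision_value
  expected <- 0.7 * exp(-0.25 * sum((s[1, ] - x)^2)) -
    0.4 * exp(-0.25 * sum((s[2, ] - x)^2)) + 0.1
  expect_equal(f, expected, tolerance = 1e-12)
  # RBF self-similarity: a lone support vector scores dual + bias at itself
  expect_equal(predict(model, toy_dataset_tibble(
    matrix(s[1, ], 1, dimnames = list(NULL, c("f1", "f2"))),
    1))$decision_value,
    0.7 - 0.4 * exp(-0.25 * 9) + 0.1, tolerance = 1e-12)
})

test_that("negating all labels negates all decision values", {
  data <- blob_data(sep = 2, seed = 7)
  flipped <- data
  flipped$label <- -data$label
  f1 <- predict(svm_train(data, C = 1, gamma = 0.3, tolerance = 1e-7),
                data)$decision_value
  f2 <- predict(svm_train(flipped, C = 1, gamma = 0.3, tolerance = 1e-7),
                flipped)$decision_value
  expect_equal(f1, -f2, tolerance = 1e-5)
})

test_that("ties in decision value resolve to the positive class", {
  model <- structure(list(support_vectors = matrix(0, 1, 1,
                              dimnames = list(NULL, "f1")),
                          dual_coefficients = 1, support_index = 1,
                          bias = -1,    # f(0) = 1*K(0,0) - 1 = 0
                          C = 1, gamma = 1, scaling = NULL, schema = NULL,
                          n_train = 1), class = "dt_svm")
  pred <- predict(model, toy_dataset_tibble(
    matrix(0, 1, dimnames = list(NULL, "f1")), 1))
  expect_equal(pred$decision_value, 0)
  expect_equal(pred$label, 1)
})

test_that("degenerate training inputs are rejected", {
  one_class <- toy_dataset_tibble(matrix(rnorm(10), 5), rep(1, 5))
  expect_error(svm_train(one_class), "both classes")
  bad <- blob_data(seed = 1)
  bad$f1[1] <- NA
  expect_error(svm_train(bad), "non-finite")
})

test_that("predict refuses mismatched schemas, naming both", {
  d <- generate_dataset(n_pos = 3, n_neg = 3, length_range = c(12, 15),
                        seed = 44)
  sdt2 <- encode_profiles(d$profiles, "sdt", LG = 2, labels = d$labels)
  sdt3 <- encode_profiles(d$profiles, "sdt", LG = 3, labels = d$labels)
  model <- svm_train(sdt2, C = 1)
  expect_error(predict(model, sdt3), "sdt \\(LG=2.*sdt \\(LG=3")
})

test_that("grid_search maximises CV accuracy with the smaller-C tie-break", {
  data <- blob_data(n_per = 10, sep = 8, seed = 10)
  gs <- grid_search(data, C_grid = c(4, 1), gamma_grid = c(0.5, 0.1),
                    folds = 5, seed = 3)
  expect_equal(gs$accuracy, 1)          # separable: some point is perfect
  # perfect accuracy everywhere here, so smallest C then smallest gamma wins
  expect_equal(gs$C, 1)
  expect_equal(gs$gamma, min(gs$cv_table$gamma[gs$cv_table$accuracy == 1]))
  expect_equal(nrow(gs$cv_table), 4)
})

test_that("grid_search is deterministic given the seed", {
  data <- blob_data(n_per = 10, sep = 1, seed = 11)
  g1 <- grid_search(data, C_grid = c(1, 4), gamma_grid = c(0.1, 1),
                    folds = 4, seed = 9)
  g2 <- grid_search(data, C_grid = c(1, 4), gamma_grid = c(0.1, 1),
                    folds = 4, seed = 9)
  expect_identical(g1$cv_table, g2$cv_table)
  expect_identical(c(g1$C, g1$gamma), c(g2$C, g2$gamma))
  expect_error(grid_search(blob_data(n_per = 3), folds = 5), "at least 5")
})

test_that("min-max scaling is fitted on training data and reapplied", {
  data <- blob_data(sep = 4, seed = 13)
  data$f1 <- data$f1 * 1000              # wild dynamic range
  model <- svm_train(data, C = 10, gamma = 1, scale_features = TRUE)
  expect_false(is.null(model$scaling))
  expect_equal(predict(model, data)$label, data$label)
})

test_that("models round-trip through the JSON bundle", {
  d <- generate_dataset(n_pos = 4, n_neg = 4, length_range = c(12, 16),
                        seed = 55)
  enc <- encode_profiles(d$profiles, "dt", LG = 2, labels = d$labels)
  model <- svm_train(enc, C = 2, gamma = 1e-4)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(predict(back, enc)$decision_value,
               predict(model, enc)$decision_value, tolerance = 1e-12)
  expect_true(same_schema(back$schema, model$schema))
})
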