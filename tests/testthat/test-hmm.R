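test_that("left-right initialisation respects the topology", {
  h <- init_left_right_hmm(2, 3, seed = 1)
  expect_equal(h$pi, c(1, 0))
  expect_equal(h$A[2, ], c(0, 1))
  for (n in c(3, 6)) {
    h <- init_left_right_hmm(n, 4, seed = 2)
    expect_equal(rowSums(h$A), rep(1, n))
    expect_equal(rowSums(h$B), rep(1, n))
    expect_true(all(h$A[lower.tri(h$A)] == 0))
    expect_true(all(h$A[col(h$A) > row(h$A) + 1] == 0))
    expect_equal(h$A[n, 1], 0)
  }
  expect_identical(init_left_right_hmm(5, 7, seed = 9),
                   init_left_right_hmm(5, 7, seed = 9))
  skip <- init_left_right_hmm(5, 4, seed = 1, allow_skip = TRUE)
  expect_true(any(skip$A[col(skip$A) == row(skip$A) + 2] > 0))
})

test_that("forward algorithm matches closed forms and path enumeration", {
  one <- structure(list(pi = 1, A = matrix(1, 1, 1),
                        B = matrix(c(0.5, 0.5), 1), n_states = 1L, k = 2L),
                   class = "gait_hmm")
  expect_equal(log_likelihood(one, c(1, 2, 1)), log(0.125))
  two <- structure(list(pi = c(1, 0),
                        A = matrix(c(0.6, 0, 0.4, 1), 2),
                        B = matrix(c(0.9, 0.2, 0.1, 0.8), 2),
                        n_states = 2L, k = 2L),
                   class = "gait_hmm")
  # brute force over both paths: 0.9 * (0.6*0.1 + 0.4*0.8)
  expect_equal(log_likelihood(two, c(1, 2)), log(0.342))
  withr::local_seed(99)
  for (rep in 1:50) {
    n <- sample(1:3, 1); k <- sample(2:4, 1)
    hmm <- random_hmm(n, k)
    obs <- sample.int(k, sample(1:6, 1), replace = TRUE)
    expect_equal(log_likelihood(hmm, obs), brute_loglik(hmm, obs),
                 tolerance = 1e-10)
  }
  expect_error(log_likelihood(two, integer(0)), "non-empty")
  expect_error(log_likelihood(two, c(1, 3)), "out of range")
})

test_that("Baum-Welch increases the likelihood and preserves structure", {
  withr::local_seed(31)
  truth <- init_left_right_hmm(3, 6, seed = 5)
  seqs <- lapply(1:40, function(i) sample_hmm_seq(truth, 15))
  fit <- train_hmm(seqs, n_states = 4, k = 6, seed = 2, max_iter = 50)
  hist <- attr(fit, "logLik_history")
  expect_true(all(diff(hist) > -1e-8))
  expect_equal(rowSums(fit$A), rep(1, 4), tolerance = 1e-9)
  expect_equal(rowSums(fit$B), rep(1, 4), tolerance = 1e-9)
  expect_true(all(fit$A[lower.tri(fit$A)] == 0))
  expect_true(all(fit$A[col(fit$A) > row(fit$A) + 1] == 0))
  expect_equal(fit$pi, c(1, 0, 0, 0))
  expect_true(all(fit$B >= 1e-9))
  expect_error(train_hmm(list(c(1, 9)), n_states = 2, k = 4), "out of range")
})

test_that("threshold follows the mean + lambda * population-sd form", {
  expect_equal(estimate_threshold(c(-10, -10), lambda = -1.28)$threshold, -10)
  thr <- estimate_threshold(c(-8, -12), lambda = -1)
  expect_equal(thr$mu, -10)
  expect_equal(thr$sigma, 2)
  expect_equal(thr$threshold, -12)
  expect_equal(estimate_threshold(c(-3, -5, -7), lambda = 0)$threshold, -5)
  # monotone increasing in lambda
  z <- c(-20, -25, -23, -31)
  lams <- seq(-3, 1, by = 0.5)
  thrs <- vapply(lams, function(l) estimate_threshold(z, l)$threshold,
                 numeric(1))
  expect_true(all(diff(thrs) > 0))
  expect_error(estimate_threshold(-5, -1), "two")
})

test_that("classification is strict: a score at the threshold is normal", {
  withr::local_seed(17)
  truth <- init_left_right_hmm(3, 5, seed = 8)
  seqs <- lapply(1:20, function(i) sample_hmm_seq(truth, 12))
  cb <- fit_codebook(matrix(runif(40), ncol = 2), k = 5, seed = 1)
  model <- fit_normality_model(seqs, cb, n_states = 3, seed = 4)
  z <- log_likelihood(model$hmm, seqs[[1]])
  model$threshold <- z
  expect_equal(classify_cycles(model, seqs[1])$label, "normal")
  model$threshold <- z + 1e-9
  expect_equal(classify_cycles(model, seqs[1])$label, "abnormal")
  # training sequences above the mean are normal for any lambda <= 0
  model2 <- fit_normality_model(seqs, cb, n_states = 3, seed = 4,
                                lambda = -0.001)
  above <- which(model2$train_loglik > model2$mu)
  got <- classify_cycles(model2, seqs[above])
  expect_true(all(got$label == "normal"))
})

test_that("sequence scoring is the minimum of rolling three-cycle means", {
  expect_equal(score_sequence(c(-1, -2, -3, -10), w = 3), -5)
  expect_equal(score_sequence(rep(-4.2, 7)), -4.2)
  expect_equal(score_sequence(c(-2, -6), w = 3), -4)
  expect_error(score_sequence(numeric(0)), "non-empty")
})

test_that("normality model JSON serialization round-trips exactly", {
  withr::local_seed(23)
  truth <- init_left_right_hmm(3, 5, seed = 8)
  seqs <- lapply(1:10, function(i) sample_hmm_seq(truth, 10))
  cb <- fit_codebook(matrix(runif(40), ncol = 2), k = 5, seed = 1)
  model <- fit_normality_model(seqs, cb, n_states = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_normality_model(model, path)
  back <- read_normality_model(path)
  expect_equal(back$hmm$A, model$hmm$A)
  expect_equal(back$hmm$B, model$hmm$B)
  expect_equal(back$threshold, model$threshold)
  expect_equal(back$codebook$centroids, model$codebook$centroids)
  # a restored model scores sequences identically
  expect_equal(log_likelihood(back$hmm, seqs[[1]]),
               log_likelihood(model$hmm, seqs[[1]]))
})
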