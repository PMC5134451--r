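test_that("k well-separated points are their own centroids", {
  x <- rbind(c(0, 0), c(5, 0), c(0, 5), c(7, 7))
  cb <- fit_codebook(x, k = 4, seed = 1)
  # zero-inertia solution: centroids equal the points up to permutation
  expect_equal(cb$inertia, 0, tolerance = 1e-12)
  perm <- apply(gaitnorm:::dist2(x, cb$centroids), 1, which.min)
  expect_equal(sort(perm), 1:4)
  expect_lt(max(abs(cb$centroids[perm, ] - x)), 1e-12)
})

test_that("k exceeding the number of distinct vectors is an error", {
  x <- matrix(rep(c(1, 2), each = 5), ncol = 2)
  expect_error(fit_codebook(x, k = 2, seed = 1), "distinct")
})

test_that("two tight blobs are recovered near their means", {
  withr::local_seed(8)
  blob <- function(center, n = 100) {
    sweep(matrix(rnorm(2 * n, 0, 0.01), ncol = 2), 2, center, `+`)
  }
  x <- rbind(blob(c(0, 0)), blob(c(1, 0)))
  cb <- fit_codebook(x, k = 2, seed = 3)
  means <- cb$centroids[order(cb$centroids[, 1]), ]
  expect_lt(max(abs(means[1, ] - colMeans(x[1:100, ]))), 0.01)
  expect_lt(max(abs(means[2, ] - colMeans(x[101:200, ]))), 0.01)
  # independent check: stats::kmeans Lloyd reaches the same inertia
  km <- stats::kmeans(x, centers = 2, nstart = 20, algorithm = "Lloyd")
  expect_equal(cb$inertia, km$tot.withinss, tolerance = 1e-6)
})

test_that("encoding maps to the nearest centroid with lowest-index ties", {
  cb <- fit_codebook(rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 2)), k = 4, seed = 1)
  # a vector equal to a centroid encodes to that centroid
  for (j in 1:4) expect_equal(encode(cb$centroids[j, ], cb), j)
  # exact tie between two centroids goes to the lower index
  mid <- (cb$centroids[1, ] + cb$centroids[2, ]) / 2
  d <- gaitnorm:::dist2(rbind(mid), cb$centroids)
  tied <- which(abs(d - min(d)) < 1e-12)
  expect_equal(encode(mid, cb), min(tied))
  # random vectors match a linear-scan oracle
  withr::local_seed(4)
  for (rep in 1:20) {
    v <- runif(2, -1, 3)
    oracle <- which.min(colSums((t(cb$centroids) - v)^2))
    expect_equal(encode(v, cb), oracle)
  }
  expect_error(encode(c(1, 2, 3), cb), "dimension")
})

test_that("cycle encoding preserves order and length", {
  sim <- simulate_gait("normal", n_strides = 4, seed = 6)
  feats <- extract_gait_features(sim$skeleton)
  cycles <- extract_cycles(sim$skeleton)
  cb <- fit_codebook(feats, k = 8, seed = 2)
  enc <- encode_cycles(cycles, feats, cb)
  expect_equal(lengths(enc$codewords), enc$n_frames)
  # frame-by-frame agreement with independent per-frame encoding
  mats <- gaitnorm:::cycle_feature_matrices(cycles, feats)
  for (i in seq_along(mats)) {
    expect_equal(enc$codewords[[i]],
                 vapply(seq_len(nrow(mats[[i]])),
                        function(r) encode(mats[[i]][r, ], cb), integer(1)))
  }
})

test_that("fitting is reproducible bit-for-bit given the seed", {
  sim <- simulate_gait("normal", n_strides = 4, seed = 6)
  feats <- extract_gait_features(sim$skeleton)
  cb1 <- fit_codebook(feats, k = 10, seed = 7)
  cb2 <- fit_codebook(feats, k = 10, seed = 7)
  expect_identical(cb1$centroids, cb2$centroids)
  codes1 <- encode(feats, cb1)
  expect_identical(codes1, encode(feats, cb1))
})

test_that("quantization error is non-increasing in k", {
  sim <- simulate_gait("normal", n_strides = 8, seed = 6)
  feats <- extract_gait_features(sim$skeleton)
  x <- as.matrix(feats[, -1])
  err <- vapply(c(4, 8, 16, 32, 43), function(k) {
    cb <- fit_codebook(x, k = k, seed = 5)
    codes <- encode(x, cb)
    mean(sqrt(rowSums((x - cb$centroids[codes, ])^2)))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-10))
})

test_that("codebook JSON serialization round-trips", {
  sim <- simulate_gait("normal", n_strides = 2, seed = 6)
  cb <- fit_codebook(extract_gait_features(sim$skeleton), k = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_codebook_json(cb, path)
  back <- read_codebook_json(path)
  expect_equal(back$centroids, cb$centroids)
  expect_equal(back$k, cb$k)
  expect_equal(back$features, cb$features)
})
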