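test_that("confusion metrics match hand arithmetic", {
  perfect <- confusion_metrics(rep(c("abnormal", "normal"), 5),
                               rep(c("abnormal", "normal"), 5))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)

  truth <- rep(c("abnormal", "normal"), c(10, 10))
  pred <- c(rep("abnormal", 9), "normal",          # tp = 9, fn = 1
            rep("normal", 8), rep("abnormal", 2))  # tn = 8, fp = 2
  m <- confusion_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 9 / 11)
  expect_equal(m$accuracy, 0.85)
})

test_that("undefined ratios warn and come back as NA", {
  w <- capture_warnings(
    m <- confusion_metrics(rep("normal", 4), rep("normal", 4))
  )
  expect_true(any(grepl("sensitivity undefined", w)))
  expect_true(any(grepl("precision undefined", w)))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  expect_error(confusion_metrics(character(0), character(0)), "non-empty")
  expect_error(confusion_metrics("sick", "normal"), "must be")
})

test_that("metrics are invariant to item order", {
  withr::local_seed(6)
  truth <- sample(c("normal", "abnormal"), 40, replace = TRUE)
  pred <- sample(c("normal", "abnormal"), 40, replace = TRUE)
  perm <- sample.int(40)
  expect_equal(confusion_metrics(truth, pred),
               confusion_metrics(truth[perm], pred[perm]))
})

test_that("AUC follows the pair-counting formulation with tie credit", {
  sep <- roc_auc_eer(c(-1, -2, -10, -12), c("normal", "normal",
                                            "abnormal", "abnormal"))
  expect_equal(sep$auc, 1)
  expect_equal(sep$eer, 0)
  ties <- roc_auc_eer(rep(-5, 6), rep(c("normal", "abnormal"), 3))
  expect_equal(ties$auc, 0.5)
  # exhaustive pair counting: normal {-1,-4}, abnormal {-3,-5} -> 3/4
  mix <- roc_auc_eer(c(-1, -4, -3, -5),
                     c("normal", "normal", "abnormal", "abnormal"))
  expect_equal(mix$auc, 3 / 4)
  expect_error(roc_auc_eer(1:3, rep("normal", 3)), "both classes")
})

test_that("pair-counting AUC equals the trapezoidal area under the ROC", {
  trap_area <- function(roc) {
    ord <- order(roc$fpr, roc$tpr)
    f <- roc$fpr[ord]; t <- roc$tpr[ord]
    sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
  }
  withr::local_seed(12)
  for (rep in 1:10) {
    scores <- round(rnorm(60), 1)  # rounding forces ties
    labels <- sample(c("normal", "abnormal"), 60, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    r <- roc_auc_eer(scores, labels)
    expect_equal(r$auc, trap_area(r$roc), tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(15)
  scores <- rnorm(80)
  labels <- sample(c("normal", "abnormal"), 80, replace = TRUE)
  ours <- roc_auc_eer(scores, labels)$auc
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("abnormal", "normal"), direction = "<",
                   quiet = TRUE)
  expect_equal(ours, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("grid search is deterministic and prefers the separable cell", {
  sim_n <- simulate_gait("normal", n_strides = 8, seed = 50)
  sim_a <- simulate_gait("shuffling", n_strides = 8, seed = 51,
                         asymmetry_ratio = 0.3)
  prep <- function(sim) {
    gaitnorm:::cycle_feature_matrices(extract_cycles(sim$skeleton),
                                      extract_gait_features(sim$skeleton))
  }
  train <- prep(sim_n)
  eval_n <- prep(simulate_gait("normal", n_strides = 6, seed = 52))
  eval_a <- prep(sim_a)
  feats <- c(eval_n, eval_a)
  labs <- rep(c("normal", "abnormal"), c(length(eval_n), length(eval_a)))

  single <- grid_search(train, feats, labs, states = 4, ks = 8, seed = 3)
  expect_equal(nrow(single$grid), 1L)
  expect_equal(c(single$best$n_states, single$best$k), c(4, 8))

  g1 <- grid_search(train, feats, labs, states = c(4, 6), ks = c(2, 10),
                    seed = 3)
  g2 <- grid_search(train, feats, labs, states = c(4, 6), ks = c(2, 10),
                    seed = 3)
  expect_equal(g1$grid, g2$grid)
  expect_equal(max(g1$grid$accuracy, na.rm = TRUE), g1$best$accuracy)
  # a k = 2 codebook is too coarse to beat a richer one here
  acc_by_k <- tapply(g1$grid$accuracy, g1$grid$k, max)
  expect_gte(acc_by_k[["10"]], acc_by_k[["2"]])
})
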