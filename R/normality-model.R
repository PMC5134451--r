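#' Normality threshold from training log-likelihoods
#'
#' The anomaly threshold is `mu + lambda * sigma`, where `mu` and `sigma` are
#' the mean and population standard deviation (divide-by-n form) of the
#' training cycles' log-likelihoods. With the default `lambda = -1.28`
#' (the inverse standard-normal CDF at probability 0.10, to two decimals)
#' the threshold sits at the 10th percentile of a Gaussian fitted to the
#' training scores, so about 10% of genuinely normal cycles are expected to
#' fall below it.
#'
#' @param zetas Numeric vector of training log-likelihoods (length >= 2).
#' @param lambda Threshold constant (default -1.28).
#' @return A list with `threshold`, `mu` and `sigma`.
#' @export
#' @examples
#' estimate_threshold(c(-8, -12), lambda = -1)$threshold # -12
estimate_threshold <- function(zetas, lambda = -1.28) {
  if (!is.numeric(zetas) || length(zetas) < 2L) {
    abort("at least two training log-likelihoods are required")
  }
  if (any(!is.finite(zetas))) abort("training log-likelihoods must be finite")
  mu <- mean(zetas)
  sigma <- sqrt(mean((zetas - mu)^2))
  list(threshold = mu + lambda * sigma, mu = mu, sigma = sigma)
}

#' Fit a normal-gait normality model
#'
#' Bundles the whole one-class detector: a left-right HMM trained on the
#' codeword sequences of normal gait cycles, the codebook that produced the
#' codewords, and the `mu + lambda * sigma` threshold estimated from the
#' training cycles' log-likelihoods.
#'
#' @param train_codes List of integer codeword sequences (one per normal
#'   training cycle).
#' @param codebook The [fit_codebook()] object used to encode the cycles.
#' @param n_states HMM states (default 24).
#' @param lambda Threshold constant (default -1.28).
#' @param seed Integer seed for HMM initialisation.
#' @param ... Passed on to [train_hmm()] (e.g. `max_iter`, `tol`,
#'   `allow_skip`).
#' @return An object of class `normality_model`: `hmm`, `codebook`,
#'   `threshold`, `mu`, `sigma`, `lambda`, `n_train`, `train_loglik`, `seed`.
#' @export
fit_normality_model <- function(train_codes, codebook, n_states = 24,
                                lambda = -1.28, seed = 1, ...) {
  stopifnot(inherits(codebook, "gait_codebook"))
  hmm <- train_hmm(train_codes, n_states = n_states, k = codebook$k,
                   seed = seed, ...)
  zetas <- vapply(train_codes, log_likelihood, numeric(1), hmm = hmm)
  thr <- estimate_threshold(zetas, lambda)
  structure(
    list(
      hmm = hmm, codebook = codebook,
      threshold = thr$threshold, mu = thr$mu, sigma = thr$sigma,
      lambda = lambda, n_train = length(train_codes), train_loglik = zetas,
      seed = as.integer(seed)
    ),
    class = "normality_model"
  )
}

#' Classify gait cycles against a normality model
#'
#' Scores each codeword sequence with the forward algorithm and flags it
#' abnormal iff its log-likelihood is strictly below the model threshold
#' (a score exactly at the threshold is normal).
#'
#' @param model A [fit_normality_model()] object.
#' @param codes A list of integer codeword sequences, or a cycle tibble with
#'   a `codewords` list-column (from [encode_cycles()]).
#' @return A tibble with columns `cycle` (index or `cycle_id`), `zeta`
#'   (log-likelihood) and `label` (`"normal"`/`"abnormal"`).
#' @export
classify_cycles <- function(model, codes) {
  stopifnot(inherits(model, "normality_model"))
  ids <- NULL
  if (is.data.frame(codes)) {
    ids <- codes$cycle_id
    codes <- codes$codewords
  }
  if (!is.list(codes)) codes <- list(codes)
  zeta <- vapply(codes, log_likelihood, numeric(1), hmm = model$hmm)
  tibble::tibble(
    cycle = ids %||% seq_along(codes),
    zeta = zeta,
    label = ifelse(zeta < model$threshold, "abnormal", "normal")
  )
}

#' Sequence-level score from per-cycle log-likelihoods
#'
#' Summarises a walking sequence by the minimum over all windows of `w`
#' consecutive cycles of the window-mean log-likelihood: the score looks for
#' the most abnormal sustained stretch while averaging out single noisy
#' cycles. Sequences with fewer than `w` cycles are scored by the mean of all
#' their cycles.
#'
#' @param zetas Numeric vector of per-cycle log-likelihoods, in cycle order.
#' @param w Window length in cycles (default 3).
#' @return A single score (lower = more abnormal).
#' @export
#' @examples
#' score_sequence(c(-1, -2, -3, -10)) # -5
score_sequence <- function(zetas, w = 3) {
  if (length(zetas) == 0L) abort("zetas must be non-empty")
  if (!is_count(w, min = 1L)) abort("w must be a positive integer")
  if (length(zetas) < w) return(mean(zetas))
  min(rowMeans(stats::embed(zetas, w)))
}

#' @export
print.normality_model <- function(x, ...) {
  cat("<normality_model> one-class gait detector\n")
  cat("  HMM:", x$hmm$n_states, "states x", x$codebook$k, "codewords\n")
  cat(sprintf("  threshold = mu + lambda*sigma = %.4f + (%.2f)*%.4f = %.4f\n",
              x$mu, x$lambda, x$sigma, x$threshold))
  cat("  trained on", x$n_train, "normal cycles\n")
  invisible(x)
}

#' Serialize a normality model to a single JSON document
#'
#' Writes topology, initial distribution, transition and emission matrices,
#' the embedded codebook, threshold statistics and seeds with full double
#' precision; [read_normality_model()] restores an identical model.
#'
#' @param model A `normality_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normality_model <- function(model, path) {
  hmm <- model$hmm
  obj <- list(
    version = 1L,
    hmm = list(
      n_states = hmm$n_states, k = hmm$k, allow_skip = hmm$allow_skip,
      pi = as.list(hmm$pi),
      A = apply(hmm$A, 1L, as.list, simplify = FALSE),
      B = apply(hmm$B, 1L, as.list, simplify = FALSE)
    ),
    codebook = list(
      k = model$codebook$k, feature_dim = model$codebook$feature_dim,
      features = as.list(model$codebook$features), seed = model$codebook$seed,
      centroids = apply(model$codebook$centroids, 1L, as.list, simplify = FALSE)
    ),
    mu = model$mu, sigma = model$sigma, lambda = model$lambda,
    threshold = model$threshold, n_train = model$n_train,
    train_loglik = as.list(model$train_loglik), seed = model$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normality model from JSON
#'
#' @param path Path written by [write_normality_model()].
#' @return A `normality_model`.
#' @export
read_normality_model <- function(path) {
  obj <- jsonlite::read_json(path)
  as_row_matrix <- function(rows) do.call(rbind, lapply(rows, unlist))
  hmm <- structure(
    list(
      pi = unlist(obj$hmm$pi),
      A = as_row_matrix(obj$hmm$A),
      B = as_row_matrix(obj$hmm$B),
      n_states = as.integer(obj$hmm$n_states),
      k = as.integer(obj$hmm$k),
      allow_skip = isTRUE(obj$hmm$allow_skip)
    ),
    class = "gait_hmm"
  )
  centroids <- as_row_matrix(obj$codebook$centroids)
  colnames(centroids) <- unlist(obj$codebook$features)
  codebook <- structure(
    list(
      centroids = centroids, k = as.integer(obj$codebook$k),
      feature_dim = as.integer(obj$codebook$feature_dim),
      features = unlist(obj$codebook$features),
      seed = as.integer(obj$codebook$seed),
      inertia = NA_real_, iter = NA_integer_
    ),
    class = "gait_codebook"
  )
  structure(
    list(
      hmm = hmm, codebook = codebook,
      threshold = obj$threshold, mu = obj$mu, sigma = obj$sigma,
      lambda = obj$lambda, n_train = as.integer(obj$n_train),
      train_loglik = unlist(obj$train_loglik), seed = as.integer(obj$seed)
    ),
    class = "normality_model"
  )
}
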