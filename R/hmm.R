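#' Initialise a left-right (Bakis) discrete HMM
#'
#' Builds a left-right hidden Markov model over codeword observations: states
#' are ordered, each state may only persist or advance to its successor
#' (`a_ij = 0` for `j < i` and `j > i + 1`; optionally one-state skips), the
#' last state is absorbing (no return to the first state), and the chain
#' always starts in state 1 (`pi = (1, 0, ..., 0)`). Self/advance masses are
#' drawn randomly per row and emission rows are seeded flat Dirichlet draws;
#' the initialisation is deterministic per seed.
#'
#' @param n_states Number of states (>= 2).
#' @param k Number of observation symbols (codewords, >= 2).
#' @param seed Integer seed.
#' @param allow_skip Also allow `i -> i + 2` transitions (default `FALSE`,
#'   the most constrained sequential topology).
#' @return An object of class `gait_hmm` with elements `pi`, `A` (`n x n`),
#'   `B` (`n x k`), `n_states`, `k`, `allow_skip`.
#' @export
init_left_right_hmm <- function(n_states, k, seed = 1, allow_skip = FALSE) {
  if (!is_count(n_states, min = 2L)) abort("n_states must be an integer >= 2")
  if (!is_count(k, min = 2L)) abort("k must be an integer >= 2")
  n <- as.integer(n_states); k <- as.integer(k)
  with_seed(seed, {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      reach <- i:min(n, i + (if (allow_skip) 2L else 1L))
      w <- rgamma(length(reach), shape = 1) + 1e-3
      A[i, reach] <- w / sum(w)
    }
    A[n, n] <- 1
    B <- matrix(rgamma(n * k, shape = 1) + 1e-3, n, k)
    B <- B / rowSums(B)
    structure(
      list(pi = c(1, rep(0, n - 1L)), A = A, B = B,
           n_states = n, k = k, allow_skip = isTRUE(allow_skip)),
      class = "gait_hmm"
    )
  })
}

check_obs <- function(obs, k) {
  obs <- as.integer(obs)
  if (length(obs) == 0L) abort("observation sequence must be non-empty")
  if (any(obs < 1L | obs > k)) {
    abort(paste0("codeword out of range 1..", k))
  }
  obs
}

#' Log-likelihood of a codeword sequence under a gait HMM
#'
#' The scaled forward algorithm: exact summation over all hidden state paths
#' of the sequence probability, accumulated in log space through per-step
#' normalisation so arbitrarily long cycles do not underflow. Natural
#' logarithm. A sequence of zero probability returns `-Inf`.
#'
#' @param hmm A `gait_hmm`.
#' @param obs Integer codeword sequence (values in `1..k`).
#' @return The log-likelihood (a non-positive number or `-Inf`).
#' @export
log_likelihood <- function(hmm, obs) {
  stopifnot(inherits(hmm, "gait_hmm"))
  obs <- check_obs(obs, hmm$k)
  alpha <- hmm$pi * hmm$B[, obs[1L]]
  ct <- sum(alpha)
  if (ct == 0) return(-Inf)
  ll <- log(ct)
  alpha <- alpha / ct
  for (t in seq_along(obs)[-1L]) {
    alpha <- as.vector(alpha %*% hmm$A) * hmm$B[, obs[t]]
    ct <- sum(alpha)
    if (ct == 0) return(-Inf)
    ll <- ll + log(ct)
    alpha <- alpha / ct
  }
  ll
}

# scaled forward-backward pass; returns per-frame posteriors (gamma),
# expected transition counts (xi_sum) and the sequence log-likelihood
forward_backward <- function(hmm, obs) {
  n <- hmm$n_states
  T_ <- length(obs)
  A <- hmm$A; B <- hmm$B
  alpha <- matrix(0, T_, n)
  cvec <- numeric(T_)
  a <- hmm$pi * B[, obs[1L]]
  cvec[1L] <- sum(a)
  if (cvec[1L] == 0) return(NULL)
  alpha[1L, ] <- a / cvec[1L]
  for (t in seq_len(T_)[-1L]) {
    a <- as.vector(alpha[t - 1L, ] %*% A) * B[, obs[t]]
    cvec[t] <- sum(a)
    if (cvec[t] == 0) return(NULL)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, T_, n)
  beta[T_, ] <- 1
  if (T_ > 1L) {
    for (t in (T_ - 1L):1L) {
      b <- as.vector(A %*% (B[, obs[t + 1L]] * beta[t + 1L, ]))
      beta[t, ] <- b / cvec[t + 1L]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, n, n)
  if (T_ > 1L) {
    for (t in seq_len(T_ - 1L)) {
      xi <- (alpha[t, ] %o% (B[, obs[t + 1L]] * beta[t + 1L, ])) * A
      xi_sum <- xi_sum + xi / sum(xi)
    }
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(cvec)))
}

#' Train a left-right gait HMM with multi-sequence Baum-Welch
#'
#' Expectation-maximisation over a set of codeword sequences (one per normal
#' gait cycle), starting from [init_left_right_hmm()]. The structural zeros of
#' the left-right topology are preserved exactly at every iteration (an EM
#' update cannot resurrect a zero transition) and the initial distribution
#' stays fixed at state 1. Training stops when the total log-likelihood
#' improves by less than `tol` or after `max_iter` iterations. After
#' convergence, emission probabilities are floored at `emission_floor` and
#' rows renormalised so that a codeword never seen in training yields a very
#' low — rather than minus-infinite — likelihood.
#'
#' @param sequences List of integer codeword sequences (values in `1..k`).
#' @param n_states Number of states (default 24).
#' @param k Number of observation symbols; defaults to the largest codeword.
#' @param seed Integer seed for the initialisation.
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Convergence tolerance on the total log-likelihood (default 1e-4).
#' @param allow_skip Allow one-state skips in the topology (default `FALSE`).
#' @param emission_floor Post-training floor on emission probabilities.
#' @return A `gait_hmm` with attributes `logLik` (final training
#'   log-likelihood), `logLik_history`, `n_iter` and `converged`.
#' @export
train_hmm <- function(sequences, n_states = 24, k = NULL, seed = 1,
                      max_iter = 200, tol = 1e-4, allow_skip = FALSE,
                      emission_floor = 1e-8) {
  if (!is.list(sequences) || length(sequences) == 0L) {
    abort("sequences must be a non-empty list of codeword vectors")
  }
  k <- k %||% max(unlist(sequences))
  sequences <- lapply(sequences, check_obs, k = k)
  hmm <- init_left_right_hmm(n_states, k, seed = seed, allow_skip = allow_skip)
  n <- hmm$n_states
  mask <- hmm$A > 0

  history <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    A_num <- matrix(0, n, n)
    gamma_trans <- numeric(n)       # sum of gamma over t < T (transition denominator)
    B_num <- matrix(0, n, hmm$k)
    total_ll <- 0
    for (obs in sequences) {
      fb <- forward_backward(hmm, obs)
      if (is.null(fb)) abort("zero-probability sequence during training")
      total_ll <- total_ll + fb$loglik
      T_ <- length(obs)
      A_num <- A_num + fb$xi_sum
      if (T_ > 1L) {
        gamma_trans <- gamma_trans + colSums(fb$gamma[-T_, , drop = FALSE])
      }
      for (t in seq_len(T_)) {
        B_num[, obs[t]] <- B_num[, obs[t]] + fb$gamma[t, ]
      }
    }
    history <- c(history, total_ll)
    if (iter > 1L && total_ll - history[iter - 1L] < tol) {
      converged <- TRUE
      break
    }
    A_new <- hmm$A
    for (i in seq_len(n)) {
      if (gamma_trans[i] > 0) A_new[i, ] <- A_num[i, ] / gamma_trans[i]
      rs <- sum(A_new[i, ])
      if (rs > 0) A_new[i, ] <- A_new[i, ] / rs else A_new[i, i] <- 1
    }
    A_new[!mask] <- 0
    A_new <- A_new / rowSums(A_new)
    B_new <- hmm$B
    state_tot <- rowSums(B_num)
    upd <- state_tot > 0
    B_new[upd, ] <- B_num[upd, , drop = FALSE] / state_tot[upd]
    hmm$A <- A_new
    hmm$B <- B_new
  }

  hmm$B <- pmax(hmm$B, emission_floor)
  hmm$B <- hmm$B / rowSums(hmm$B)
  attr(hmm, "logLik") <- history[length(history)]
  attr(hmm, "logLik_history") <- history
  attr(hmm, "n_iter") <- length(history)
  attr(hmm, "converged") <- converged
  hmm
}

#' @export
print.gait_hmm <- function(x, ...) {
  cat("<gait_hmm> left-right HMM:", x$n_states, "states,", x$k,
      "observation symbols\n")
  ll <- attr(x, "logLik")
  if (!is.null(ll)) {
    cat("  training logLik:", format(ll, digits = 8),
        " iterations:", attr(x, "n_iter"),
        " converged:", attr(x, "converged"), "\n")
  }
  invisible(x)
}
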