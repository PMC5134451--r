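# broom-style tidiers for the package's fitted objects

#' Tidy a gait HMM into a long parameter table
#'
#' @param x A `gait_hmm`.
#' @param matrix `"transition"` (non-zero `a_ij` entries) or `"emission"`
#'   (all `b` entries).
#' @param ... Unused.
#' @return A tibble of parameters.
#' @export
tidy.gait_hmm <- function(x, matrix = c("transition", "emission"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "transition") {
    idx <- which(x$A > 0, arr.ind = TRUE)
    tibble::tibble(
      from_state = as.integer(idx[, 1L]),
      to_state = as.integer(idx[, 2L]),
      probability = x$A[idx]
    ) |> dplyr::arrange(.data$from_state, .data$to_state)
  } else {
    tidyr::expand_grid(state = seq_len(x$n_states), codeword = seq_len(x$k)) |>
      dplyr::mutate(probability = x$B[cbind(.data$state, .data$codeword)])
  }
}

#' One-row summary of a gait HMM
#'
#' @param x A `gait_hmm`.
#' @param ... Unused.
#' @return A tibble with `n_states`, `k`, training `logLik`, `n_iter`,
#'   `converged`.
#' @export
glance.gait_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states, k = x$k,
    logLik = attr(x, "logLik") %||% NA_real_,
    n_iter = attr(x, "n_iter") %||% NA_integer_,
    converged = attr(x, "converged") %||% NA
  )
}

#' Per-training-cycle log-likelihoods of a normality model
#'
#' @param x A `normality_model`.
#' @param ... Unused.
#' @return A tibble `cycle, zeta, below_threshold`.
#' @export
tidy.normality_model <- function(x, ...) {
  tibble::tibble(
    cycle = seq_along(x$train_loglik),
    zeta = x$train_loglik,
    below_threshold = x$train_loglik < x$threshold
  )
}

#' One-row summary of a normality model
#'
#' @param x A `normality_model`.
#' @param ... Unused.
#' @return A tibble with `mu`, `sigma`, `lambda`, `threshold`, `n_train`,
#'   `n_states`, `k`.
#' @export
glance.normality_model <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma = x$sigma, lambda = x$lambda, threshold = x$threshold,
    n_train = x$n_train, n_states = x$hmm$n_states, k = x$codebook$k
  )
}

#' ROC curve points
#'
#' @param x A `gait_roc` from [roc_auc_eer()].
#' @param ... Unused.
#' @return The ROC tibble `threshold, fpr, tpr`.
#' @export
tidy.gait_roc <- function(x, ...) x$roc

#' One-row AUC/EER summary
#'
#' @param x A `gait_roc`.
#' @param ... Unused.
#' @return A tibble with `auc` and `eer`.
#' @export
glance.gait_roc <- function(x, ...) tibble::tibble(auc = x$auc, eer = x$eer)

#' Grid-search cells
#'
#' @param x A `gait_grid` from [grid_search()].
#' @param ... Unused.
#' @return The grid tibble `n_states, k, accuracy`.
#' @export
tidy.gait_grid <- function(x, ...) x$grid

#' Best grid-search cell
#'
#' @param x A `gait_grid`.
#' @param ... Unused.
#' @return A one-row tibble `n_states, k, accuracy`.
#' @export
glance.gait_grid <- function(x, ...) tibble::as_tibble(x$best)

#' Codebook centroids in long form
#'
#' @param x A `gait_codebook`.
#' @param ... Unused.
#' @return A tibble `codeword, feature, value`.
#' @export
tidy.gait_codebook <- function(x, ...) {
  tibble::as_tibble(x$centroids) |>
    dplyr::mutate(codeword = dplyr::row_number(), .before = 1L) |>
    tidyr::pivot_longer(-"codeword", names_to = "feature", values_to = "value")
}

#' Per-cycle results of an end-to-end run
#'
#' @param x A `gait_screen` from [run_end_to_end()].
#' @param ... Unused.
#' @return The per-cycle tibble `sequence, cycle_id, truth, zeta, prediction`.
#' @export
tidy.gait_screen <- function(x, ...) x$cycles

#' One-row report of an end-to-end run
#'
#' @param x A `gait_screen`.
#' @param ... Unused.
#' @return The report tibble (confusion metrics, `auc`, `eer`).
#' @export
glance.gait_screen <- function(x, ...) x$report
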