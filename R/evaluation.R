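as_gait_label <- function(x, arg = "labels") {
  x <- as.character(x)
  bad <- setdiff(unique(x), c("normal", "abnormal"))
  if (length(bad) > 0L) {
    abort(paste0(arg, " must be 'normal' or 'abnormal'; got: ",
                 paste(bad, collapse = ", ")))
  }
  x
}

#' Confusion-matrix metrics for abnormal-gait detection
#'
#' The positive class is `"abnormal"`: sensitivity (recall) is the correct
#' detection rate of abnormal cycles and specificity that of normal cycles.
#' A metric with a zero denominator is reported as `NA` with a warning,
#' never silently as 0.
#'
#' @param truth,predictions Equal-length vectors of `"normal"`/`"abnormal"`.
#' @return A one-row tibble with `tp, fp, tn, fn, precision,
#'   sensitivity, specificity, f1, accuracy`.
#' @export
#' @examples
#' confusion_metrics(
#'   rep(c("abnormal", "normal"), c(2, 2)),
#'   c("abnormal", "normal", "normal", "normal")
#' )
confusion_metrics <- function(truth, predictions) {
  truth <- as_gait_label(truth, "truth")
  predictions <- as_gait_label(predictions, "predictions")
  if (length(truth) != length(predictions) || length(truth) == 0L) {
    abort("truth and predictions must be non-empty and of equal length")
  }
  tp <- sum(truth == "abnormal" & predictions == "abnormal")
  fp <- sum(truth == "normal" & predictions == "abnormal")
  tn <- sum(truth == "normal" & predictions == "normal")
  fn <- sum(truth == "abnormal" & predictions == "normal")

  ratio <- function(num, den, name) {
    if (den == 0) {
      warn(paste0(name, " undefined (zero denominator); reported as NA"))
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  sensitivity <- ratio(tp, tp + fn, "sensitivity")
  specificity <- ratio(tn, tn + fp, "specificity")
  f1 <- if (isTRUE(precision + sensitivity > 0)) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else {
    warn("f1 undefined (zero denominator); reported as NA")
    NA_real_
  }
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    precision = precision, sensitivity = sensitivity,
    specificity = specificity, f1 = f1,
    accuracy = (tp + tn) / length(truth)
  )
}

#' ROC curve, AUC and equal error rate for log-likelihood scores
#'
#' Scores are log-likelihoods where higher means more normal; a cycle is
#' called abnormal when its score falls strictly below a threshold, and the
#' ROC sweeps that threshold over all values. The AUC is computed by the
#' rank (pair-counting) formulation with half credit for ties — the
#' probability that a random abnormal cycle scores below a random normal
#' one — which equals the trapezoidal area under the swept curve. The EER is
#' the rate at which the false-positive rate equals the false-negative rate,
#' linearly interpolated between adjacent ROC points.
#'
#' @param scores Numeric log-likelihood scores.
#' @param labels `"normal"`/`"abnormal"` per score; both classes required.
#' @return An object of class `gait_roc`: `auc`, `eer` and a tibble `roc`
#'   with `threshold, fpr, tpr`.
#' @export
roc_auc_eer <- function(scores, labels) {
  labels <- as_gait_label(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  is_ab <- labels == "abnormal"
  n_a <- sum(is_ab); n_n <- sum(!is_ab)
  if (n_a == 0L || n_n == 0L) abort("both classes must be present")

  # rank formulation: P(score_abnormal < score_normal) + 1/2 ties
  r <- rank(scores)
  auc <- (sum(r[!is_ab]) - n_n * (n_n + 1) / 2) / (n_n * n_a)

  thr <- c(sort(unique(scores)), Inf)
  roc <- tibble::tibble(
    threshold = c(-Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!is_ab] < t), numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[is_ab] < t), numeric(1)))
  )

  # EER: walk the curve until fpr >= 1 - tpr, interpolate on the segment
  d <- roc$fpr - (1 - roc$tpr)
  j <- which(d >= 0)[1L]
  eer <- if (j == 1L) {
    roc$fpr[1L]
  } else {
    f1 <- roc$fpr[j - 1L]; t1 <- roc$tpr[j - 1L]
    df <- roc$fpr[j] - f1; dt <- roc$tpr[j] - t1
    s <- (1 - t1 - f1) / (df + dt)
    f1 + s * df
  }
  structure(list(auc = auc, eer = eer, roc = roc), class = "gait_roc")
}

#' @export
print.gait_roc <- function(x, ...) {
  cat(sprintf("<gait_roc> AUC = %.4f, EER = %.4f (%d thresholds)\n",
              x$auc, x$eer, nrow(x$roc)))
  invisible(x)
}

#' Model-selection grid over HMM states and codebook sizes
#'
#' For every `(n_states, k)` combination: fit a codebook of size `k` on the
#' pooled training cycle features, encode all cycles, train a left-right HMM
#' on the training cycles, estimate the `mu + lambda * sigma` threshold, and
#' classify the labelled evaluation cycles; the cell records the pooled
#' accuracy. Deterministic per seed. A cell whose training fails is recorded
#' as `NA` rather than aborting the search. Ties on accuracy are broken
#' toward fewer states, then fewer codewords (cheaper online models).
#'
#' @param train_features List of per-cycle feature matrices (normal cycles).
#' @param eval_features List of per-cycle feature matrices to classify.
#' @param eval_labels `"normal"`/`"abnormal"` per evaluation cycle.
#' @param states Integer vector of state counts (default `6:30`).
#' @param ks Integer vector of codebook sizes (default `8:45`).
#' @param lambda Threshold constant (default -1.28).
#' @param seed Integer seed.
#' @param ... Passed to [train_hmm()].
#' @return An object of class `gait_grid`: tibble `grid`
#'   (`n_states, k, accuracy`), `best` (one-row tibble) and `best_model`.
#' @export
grid_search <- function(train_features, eval_features, eval_labels,
                        states = 6:30, ks = 8:45, lambda = -1.28,
                        seed = 1, ...) {
  eval_labels <- as_gait_label(eval_labels, "eval_labels")
  if (length(states) == 0L || length(ks) == 0L) {
    abort("states and ks must be non-empty")
  }
  if (length(eval_features) != length(eval_labels)) {
    abort("eval_features and eval_labels must have equal length")
  }
  cells <- tidyr::expand_grid(n_states = sort(unique(states)),
                              k = sort(unique(ks)))
  best_model <- NULL
  best_key <- NULL
  acc <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    acc[i] <- tryCatch({
      cb <- fit_codebook(do.call(rbind, train_features), k = cells$k[i],
                         seed = seed)
      train_codes <- lapply(train_features, encode, codebook = cb)
      eval_codes <- lapply(eval_features, encode, codebook = cb)
      model <- fit_normality_model(train_codes, cb,
                                   n_states = cells$n_states[i],
                                   lambda = lambda, seed = seed, ...)
      pred <- classify_cycles(model, eval_codes)$label
      a <- mean(pred == eval_labels)
      key <- c(-a, cells$n_states[i], cells$k[i])
      if (is.null(best_key) || order_key_lt(key, best_key)) {
        best_key <- key
        best_model <- model
      }
      a
    }, error = function(e) NA_real_)
  }
  cells$accuracy <- acc
  ord <- order(-cells$accuracy, cells$n_states, cells$k, na.last = TRUE)
  best <- cells[ord[1L], , drop = FALSE]
  structure(
    list(grid = cells, best = best, best_model = best_model),
    class = "gait_grid"
  )
}

# lexicographic strictly-less comparison of numeric keys
order_key_lt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.gait_grid <- function(x, ...) {
  cat("<gait_grid>", nrow(x$grid), "cells; best: ",
      x$best$n_states, "states x", x$best$k, "codewords, accuracy",
      format(x$best$accuracy, digits = 4), "\n")
  invisible(x)
}

#' Write a grid-search result as a CSV matrix
#'
#' Rows are state counts, columns codebook sizes, cells accuracies —
#' the layout of the usual model-selection heatmaps.
#'
#' @param grid A `gait_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  wide <- tidyr::pivot_wider(grid$grid, names_from = "k",
                             values_from = "accuracy", names_prefix = "k")
  readr::write_csv(wide, path)
  invisible(path)
}
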