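#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end detector with its default:
#' smoothing factor `alpha = 0.2`, sliding window 5, minimum cycle span 10
#' frames, codebook size `k = 43`, `n_states = 24`, threshold constant
#' `lambda = -1.28` and a 3/4 train fraction of the normal cycles (the
#' remainder is held out for evaluation).
#'
#' @param alpha Exponential smoothing factor in `(0, 1]`.
#' @param window Odd sliding-window length for boundary detection.
#' @param min_cycle_frames Minimum cycle span in frames.
#' @param k Codebook size (HMM observation symbols).
#' @param n_states HMM states.
#' @param lambda Threshold constant.
#' @param seed Integer seed driving every random stage.
#' @param train_fraction Fraction of normal cycles used for training.
#' @param sphere_compat Mask the two-feet angle on reduced skeletons.
#' @param allow_skip Allow one-state skips in the HMM topology.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.2, window = 5, min_cycle_frames = 10,
                            k = 43, n_states = 24, lambda = -1.28, seed = 1,
                            train_fraction = 0.75, sphere_compat = FALSE,
                            allow_skip = FALSE) {
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  if (!is_count(window, 3L) || window %% 2L == 0L) abort("window must be odd >= 3")
  if (!is_count(min_cycle_frames, 2L)) abort("min_cycle_frames must be >= 2")
  if (!is_count(k, 2L)) abort("k must be an integer >= 2")
  if (!is_count(n_states, 2L)) abort("n_states must be an integer >= 2")
  if (!is_number(lambda)) abort("lambda must be a number")
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  structure(
    list(alpha = alpha, window = window, min_cycle_frames = min_cycle_frames,
         k = k, n_states = n_states, lambda = lambda, seed = as.integer(seed),
         train_fraction = train_fraction, sphere_compat = isTRUE(sphere_compat),
         allow_skip = isTRUE(allow_skip)),
    class = "pipeline_config"
  )
}

# features + cycles + per-cycle feature matrices for one skeleton sequence
prepare_sequence <- function(skeleton, config, id = "seq") {
  feats <- extract_gait_features(skeleton, sphere_compat = config$sphere_compat)
  cycles <- extract_cycles(skeleton, alpha = config$alpha,
                           window = config$window,
                           min_cycle_frames = config$min_cycle_frames)
  mats <- if (nrow(cycles) > 0L) cycle_feature_matrices(cycles, feats) else list()
  list(id = id, features = feats, cycles = cycles, matrices = mats)
}

as_skeleton_list <- function(x) {
  if (is.data.frame(x)) x <- list(x)
  if (inherits(x, "gait_simulation")) x <- list(x$skeleton)
  lapply(x, function(s) if (inherits(s, "gait_simulation")) s$skeleton else s)
}

#' Run the full abnormal-gait detection experiment
#'
#' End-to-end pipeline: per-frame features, gait-cycle segmentation, a
#' seeded train/hold-out split of the normal cycles, codebook fitting on the
#' training cycles only (no leakage), left-right HMM training, threshold
#' estimation, and classification of the held-out normal cycles plus all
#' cycles of the abnormal sequences. Every random stage derives from
#' `config$seed`, so the run — including any files written — is reproducible
#' byte for byte.
#'
#' @param normal A skeleton tibble, a [simulate_gait()] object, or a list of
#'   either: the normal-gait recordings.
#' @param abnormal Like `normal`; sequences whose cycles are all labelled
#'   abnormal in the evaluation (may be empty).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes `model.json`,
#'   `report.json`, `cycles.csv` and `run.log`.
#' @return An object of class `gait_screen`: `model` (the fitted
#'   [fit_normality_model()] object), `report` (one-row tibble of confusion
#'   metrics plus `auc` and `eer`), `cycles` (per-evaluated-cycle tibble with
#'   `sequence, cycle_id, truth, zeta, prediction`), `roc` and `config`.
#' @export
run_end_to_end <- function(normal, abnormal = list(),
                           config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  normal <- as_skeleton_list(normal)
  abnormal <- as_skeleton_list(abnormal)
  if (length(normal) == 0L) abort("at least one normal sequence is required")

  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  prep_n <- purrr::imap(normal, function(s, i) {
    prepare_sequence(s, config, id = paste0("normal_", i))
  })
  prep_a <- purrr::imap(abnormal, function(s, i) {
    prepare_sequence(s, config, id = paste0("abnormal_", i))
  })
  normal_mats <- purrr::flatten(purrr::map(prep_n, "matrices"))
  say("segmented ", length(normal_mats), " normal cycles from ",
      length(normal), " sequence(s)")
  if (length(normal_mats) < 4L) abort("too few normal cycles to train on")

  n_train <- max(2L, floor(config$train_fraction * length(normal_mats)))
  train_idx <- with_seed(derive_seed(config$seed, 11L),
                         sort(sample.int(length(normal_mats), n_train)))
  train_mats <- normal_mats[train_idx]
  held_mats <- normal_mats[-train_idx]
  say("training on ", length(train_mats), " cycles; holding out ",
      length(held_mats), " normal cycles")

  codebook <- fit_codebook(do.call(rbind, train_mats), k = config$k,
                           seed = derive_seed(config$seed, 21L))
  train_codes <- lapply(train_mats, encode, codebook = codebook)
  model <- fit_normality_model(
    train_codes, codebook, n_states = config$n_states,
    lambda = config$lambda, seed = derive_seed(config$seed, 31L),
    allow_skip = config$allow_skip
  )
  say(sprintf("trained HMM (%d states x %d codewords); threshold %.4f (mu %.4f, sigma %.4f)",
              config$n_states, config$k, model$threshold, model$mu, model$sigma))

  eval_tbl <- dplyr::bind_rows(
    tibble::tibble(
      sequence = "normal_heldout",
      cycle_id = seq_along(held_mats),
      truth = "normal",
      mat = held_mats
    ),
    purrr::map_dfr(prep_a, function(p) {
      tibble::tibble(
        sequence = p$id,
        cycle_id = p$cycles$cycle_id,
        truth = "abnormal",
        mat = p$matrices
      )
    })
  )
  if (nrow(eval_tbl) == 0L) abort("no cycles to evaluate")
  eval_codes <- lapply(eval_tbl$mat, encode, codebook = codebook)
  scored <- classify_cycles(model, eval_codes)
  cycles <- tibble::tibble(
    sequence = eval_tbl$sequence,
    cycle_id = eval_tbl$cycle_id,
    truth = eval_tbl$truth,
    zeta = scored$zeta,
    prediction = scored$label
  )

  report <- confusion_metrics(cycles$truth, cycles$prediction)
  roc <- NULL
  if (length(unique(cycles$truth)) == 2L) {
    roc <- roc_auc_eer(cycles$zeta, cycles$truth)
    report$auc <- roc$auc
    report$eer <- roc$eer
  }
  say(sprintf("evaluated %d cycles: accuracy %.4f%s", nrow(cycles),
              report$accuracy,
              if (!is.null(roc)) sprintf(", AUC %.4f, EER %.4f", roc$auc, roc$eer) else ""))

  result <- structure(
    list(model = model, report = report, cycles = cycles, roc = roc,
         config = config),
    class = "gait_screen"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_normality_model(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(as.list(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(cycles, file.path(out_dir, "cycles.csv"))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  result
}

#' @export
print.gait_screen <- function(x, ...) {
  cat("<gait_screen> end-to-end abnormal-gait detection run\n")
  print(x$model)
  cat("  evaluated", nrow(x$cycles), "cycles\n")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' Run the reference synthetic detection study
#'
#' The package's self-contained stand-in for a clinical evaluation: simulate
#' normal walking plus the three one-sided/reduced-stride abnormal gait types,
#' train the detector on `n_train` normal cycles, and evaluate it on
#' `n_eval_normal` held-out normal cycles plus `n_per_abnormal` cycles of each
#' abnormal type. All data generation, the train/hold-out split, the codebook
#' and the HMM derive deterministically from `seed`.
#'
#' @param seed Integer seed for the whole study.
#' @param k Codebook size (default 16, a deliberately small online model).
#' @param n_states HMM states (default 12).
#' @param lambda Threshold constant (default -1.28).
#' @param n_train Normal training cycles (default 150).
#' @param n_eval_normal Held-out normal evaluation cycles (default 50).
#' @param n_per_abnormal Evaluation cycles per abnormal type (default 50).
#' @param n_strides Strides per simulated sequence (default 26).
#' @param abnormal_types Abnormal gait types evaluated (default asymmetric,
#'   stiff_knee, shuffling).
#' @return A `gait_screen`-like list: `model`, `report` (confusion metrics
#'   plus `auc`, `eer`), `cycles` (per-cycle tibble with the generating
#'   `gait_type`), `roc`.
#' @export
run_synthetic_study <- function(seed = 1, k = 16, n_states = 12,
                                lambda = -1.28, n_train = 150,
                                n_eval_normal = 50, n_per_abnormal = 50,
                                n_strides = 26,
                                abnormal_types = c("asymmetric", "stiff_knee",
                                                   "shuffling")) {
  config <- pipeline_config(k = k, n_states = n_states, lambda = lambda,
                            seed = seed)
  prep <- function(skel) {
    feats <- extract_gait_features(skel)
    cycles <- extract_cycles(skel, alpha = config$alpha,
                             window = config$window,
                             min_cycle_frames = config$min_cycle_frames)
    cycle_feature_matrices(cycles, feats)
  }

  # enough normal sequences for n_train + n_eval_normal cycles
  n_needed <- n_train + n_eval_normal
  normal_mats <- list()
  i <- 0L
  while (length(normal_mats) < n_needed && i < 50L) {
    i <- i + 1L
    sim <- simulate_gait("normal", n_strides = n_strides,
                         seed = derive_seed(seed, 100L + i))
    normal_mats <- c(normal_mats, prep(sim$skeleton))
  }
  normal_mats <- normal_mats[seq_len(n_needed)]
  train_idx <- with_seed(derive_seed(seed, 11L),
                         sort(sample.int(n_needed, n_train)))
  train_mats <- normal_mats[train_idx]
  held_mats <- normal_mats[-train_idx]

  abn_mats <- list()
  abn_type <- character(0)
  for (j in seq_along(abnormal_types)) {
    g <- abnormal_types[j]
    mats <- list()
    i <- 0L
    while (length(mats) < n_per_abnormal && i < 50L) {
      i <- i + 1L
      sim <- simulate_gait(g, n_strides = n_strides,
                           seed = derive_seed(seed, 200L + 10L * j + i))
      mats <- c(mats, prep(sim$skeleton))
    }
    mats <- mats[seq_len(n_per_abnormal)]
    abn_mats <- c(abn_mats, mats)
    abn_type <- c(abn_type, rep(g, n_per_abnormal))
  }

  codebook <- fit_codebook(do.call(rbind, train_mats), k = k,
                           seed = derive_seed(seed, 21L))
  train_codes <- lapply(train_mats, encode, codebook = codebook)
  model <- fit_normality_model(train_codes, codebook, n_states = n_states,
                               lambda = lambda,
                               seed = derive_seed(seed, 31L))

  eval_mats <- c(held_mats, abn_mats)
  truth <- rep(c("normal", "abnormal"), c(length(held_mats), length(abn_mats)))
  gait_type <- c(rep("normal", length(held_mats)), abn_type)
  scored <- classify_cycles(model, lapply(eval_mats, encode, codebook = codebook))
  cycles <- tibble::tibble(
    cycle = seq_along(eval_mats), gait_type = gait_type, truth = truth,
    zeta = scored$zeta, prediction = scored$label
  )
  report <- confusion_metrics(cycles$truth, cycles$prediction)
  roc <- roc_auc_eer(cycles$zeta, cycles$truth)
  report$auc <- roc$auc
  report$eer <- roc$eer
  structure(
    list(model = model, report = report, cycles = cycles, roc = roc,
         config = config),
    class = "gait_screen"
  )
}
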