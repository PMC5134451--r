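#' Foot-to-foot distance signal
#'
#' Per-frame 3D Euclidean distance between the two feet, the quasi-periodic
#' signal whose local maxima (double-support instants) delimit gait cycles.
#' On reduced 15-joint skeletons the ankle joints are substituted for the
#' missing feet (recorded in the `joints_used` attribute).
#'
#' @param skeleton A validated skeleton tibble.
#' @return A tibble with columns `frame` and `distance` (meters).
#' @export
foot_distance <- function(skeleton) {
  skeleton <- validate_skeleton(skeleton)
  if (joint_mode(skeleton) == "full") {
    l <- joint_xyz(skeleton, "FootLeft"); r <- joint_xyz(skeleton, "FootRight")
    used <- "feet"
  } else {
    l <- joint_xyz(skeleton, "AnkleLeft"); r <- joint_xyz(skeleton, "AnkleRight")
    used <- "ankles"
  }
  d <- l - r
  out <- tibble::tibble(
    frame = sort(unique(skeleton$frame)),
    distance = unname(sqrt(rowSums(d * d)))
  )
  attr(out, "joints_used") <- used
  out
}

#' Exponential smoothing
#'
#' First-order exponential smoothing of a signal:
#' `s_t = x_t` at `t = 0` and `s_t = alpha * x_t + (1 - alpha) * s_{t-1}`
#' afterwards. `alpha = 1` returns the input unchanged (useful for testing
#' detection on noiseless signals); the operational range is `0 < alpha < 1`.
#'
#' @param x Numeric vector (non-empty).
#' @param alpha Smoothing factor in `(0, 1]`.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' exponential_smooth(c(1, 2, 3), 0.2) # 1, 1.2, 1.56
exponential_smooth <- function(x, alpha) {
  if (length(x) == 0L) abort("x must be non-empty")
  if (!is_number(alpha) || alpha <= 0 || alpha > 1) {
    abort("alpha must be in (0, 1]")
  }
  if (length(x) == 1L) return(x)
  rest <- stats::filter(alpha * x[-1L], 1 - alpha, method = "recursive",
                        init = x[1L])
  c(x[1L], as.numeric(rest))
}

#' Detect gait-cycle boundaries from a smoothed distance signal
#'
#' Slides a window of odd length `window` over the signal; a position is a
#' cycle boundary iff its value is the strict maximum of the window centered
#' on it (windows fully inside the signal). Plateau ties yield no boundary.
#' This centered formulation equals an online trailing window of the same
#' length with a fixed `(window - 1) / 2`-frame reporting delay.
#'
#' @param s Numeric vector, e.g. the `smoothed` distance signal.
#' @param window Odd integer window length, at least 3.
#' @return Strictly increasing integer vector of boundary positions
#'   (1-based indices into `s`); may be empty.
#' @export
#' @examples
#' detect_cycle_boundaries(c(0, 1, 2, 1, 0, 1, 2, 1, 0), window = 5) # 3, 7
detect_cycle_boundaries <- function(s, window = 5) {
  if (!is_count(window, min = 3L) || window %% 2L == 0L) {
    abort("window must be an odd integer >= 3")
  }
  n <- length(s)
  if (n < window) return(integer(0))
  h <- (window - 1L) / 2L
  centers <- (h + 1L):(n - h)
  is_max <- vapply(centers, function(i) {
    w <- s[(i - h):(i + h)]
    s[i] > max(w[-(h + 1L)])
  }, logical(1))
  centers[is_max]
}

#' Pair consecutive boundaries into gait cycles
#'
#' Each pair of consecutive boundary frames `[b_i, b_{i+1}]` (both inclusive;
#' the shared double-support frame belongs to both neighbouring cycles) forms
#' one gait cycle. Cycles spanning fewer than `min_cycle_frames` frames are
#' dropped: short spurious segments arise from residual noise in foot
#' localisation.
#'
#' @param boundaries Sorted numeric vector of boundary frame indices.
#' @param min_cycle_frames Minimum frame count (inclusive span) of a kept
#'   cycle; default 10.
#' @return A tibble `cycle_id, start_frame, end_frame, n_frames` (possibly
#'   zero rows when fewer than two boundaries are given).
#' @export
segment_cycles <- function(boundaries, min_cycle_frames = 10) {
  if (!is_count(min_cycle_frames, min = 2L)) {
    abort("min_cycle_frames must be an integer >= 2")
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    abort("boundaries must be strictly increasing")
  }
  if (length(boundaries) < 2L) {
    return(tibble::tibble(
      cycle_id = integer(0), start_frame = numeric(0),
      end_frame = numeric(0), n_frames = numeric(0)
    ))
  }
  out <- tibble::tibble(
    start_frame = boundaries[-length(boundaries)],
    end_frame = boundaries[-1L]
  )
  out$n_frames <- out$end_frame - out$start_frame + 1
  out <- out[out$n_frames >= min_cycle_frames, , drop = FALSE]
  out$cycle_id <- seq_len(nrow(out))
  out[, c("cycle_id", "start_frame", "end_frame", "n_frames")]
}

#' Segment a skeleton sequence into gait cycles
#'
#' Full segmentation pipeline: foot-to-foot distance, exponential smoothing,
#' strict-maximum boundary detection and pairing into cycles.
#'
#' @param skeleton A validated skeleton tibble.
#' @param alpha Smoothing factor (default 0.2).
#' @param window Odd sliding-window length (default 5).
#' @param min_cycle_frames Minimum cycle span in frames (default 10).
#' @return A cycle tibble as from [segment_cycles()], with the distance
#'   signal attached as attribute `signal` (tibble
#'   `frame, raw, smoothed`) and the boundary frames as attribute
#'   `boundary_frames`.
#' @export
extract_cycles <- function(skeleton, alpha = 0.2, window = 5,
                           min_cycle_frames = 10) {
  dist <- foot_distance(skeleton)
  smoothed <- exponential_smooth(dist$distance, alpha)
  pos <- detect_cycle_boundaries(smoothed, window)
  frames <- dist$frame[pos]
  cycles <- segment_cycles(frames, min_cycle_frames)
  attr(cycles, "signal") <- tibble::tibble(
    frame = dist$frame, raw = dist$distance, smoothed = smoothed
  )
  attr(cycles, "boundary_frames") <- frames
  cycles
}

# list of per-cycle feature matrices (rows = frames in [start, end]),
# restricted to feature columns without any NA (masked features dropped)
cycle_feature_matrices <- function(cycles, features) {
  keep <- gait_feature_names[vapply(
    gait_feature_names, function(f) !anyNA(features[[f]]), logical(1)
  )]
  if (length(keep) == 0L) abort("no complete feature columns available")
  m <- as.matrix(features[, keep, drop = FALSE])
  rownames(m) <- features$frame
  purrr::map2(cycles$start_frame, cycles$end_frame, function(s, e) {
    m[features$frame >= s & features$frame <= e, , drop = FALSE]
  })
}
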