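# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force / naive so it cannot share a
# defect with the implementation it checks.

# exhaustive-path HMM likelihood: sum over all n^T state paths
brute_loglik <- function(hmm, obs) {
  n <- hmm$n_states
  paths <- expand.grid(rep(list(seq_len(n)), length(obs)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    p <- hmm$pi[s[1]] * hmm$B[s[1], obs[1]]
    for (t in seq_along(obs)[-1]) {
      p <- p * hmm$A[s[t - 1], s[t]] * hmm$B[s[t], obs[t]]
    }
    total <- total + p
  }
  log(total)
}

# random stochastic HMM (not necessarily left-right) for forward-oracle tests
random_hmm <- function(n, k) {
  norm_rows <- function(m) m / rowSums(m)
  structure(
    list(
      pi = as.vector(norm_rows(matrix(runif(n), 1))),
      A = norm_rows(matrix(runif(n * n), n)),
      B = norm_rows(matrix(runif(n * k), n)),
      n_states = n, k = k, allow_skip = FALSE
    ),
    class = "gait_hmm"
  )
}

# sample observation sequences from a known HMM (the generative truth for
# the Baum-Welch parameter-recovery test)
sample_hmm_seq <- function(hmm, len) {
  s <- sample.int(hmm$n_states, 1, prob = hmm$pi)
  obs <- integer(len)
  for (t in seq_len(len)) {
    obs[t] <- sample.int(hmm$k, 1, prob = hmm$B[s, ])
    if (t < len) s <- sample.int(hmm$n_states, 1, prob = hmm$A[s, ])
  }
  obs
}

# unoriented plane-normal via total least squares (SVD), for the two-feet
# angle oracle: returns the angle between the two fitted plane normals,
# folded into [0, pi/2] since plane equations carry no orientation
plane_fit_angle <- function(left_pts, right_pts) {
  fit_normal <- function(pts) {
    centered <- scale(pts, center = TRUE, scale = FALSE)
    svd(centered)$v[, 3]
  }
  nl <- fit_normal(left_pts)
  nr <- fit_normal(right_pts)
  ang <- acos(min(1, max(-1, abs(sum(nl * nr)))))
  ang
}

# random valid skeleton tibble (9 lower-body joints, optional feet)
random_skeleton <- function(n_frames = 4, feet = TRUE) {
  joints <- if (feet) lower_body_joints else
    setdiff(lower_body_joints, c("FootLeft", "FootRight"))
  tibble::tibble(
    frame = rep(0:(n_frames - 1), each = length(joints)),
    joint = rep(joints, times = n_frames),
    x = round(runif(n_frames * length(joints), -1, 1), 6),
    y = round(runif(n_frames * length(joints), 0, 2), 6),
    z = round(runif(n_frames * length(joints), 1, 4), 6)
  )
}

# one fully specified frame with the 9 lower-body joints at given or default
# positions; `override` is a named list joint -> c(x, y, z)
one_frame_skeleton <- function(override = list(), frame = 0) {
  base <- list(
    HipCenter = c(0, 1.0, 0),
    HipLeft = c(-0.15, 0.9, 0), HipRight = c(0.15, 0.9, 0),
    KneeLeft = c(-0.15, 0.45, 0.05), KneeRight = c(0.15, 0.45, -0.05),
    AnkleLeft = c(-0.15, 0.05, 0.02), AnkleRight = c(0.15, 0.05, -0.02),
    FootLeft = c(-0.15, 0.0, 0.15), FootRight = c(0.15, 0.0, -0.15)
  )
  for (j in names(override)) base[[j]] <- override[[j]]
  tibble::tibble(
    frame = frame,
    joint = names(base),
    x = vapply(base, `[`, numeric(1), 1),
    y = vapply(base, `[`, numeric(1), 2),
    z = vapply(base, `[`, numeric(1), 3)
  )
}

# random proper rotation matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply similarity transform (rotation R, translation tr, scale s) to a
# long-format skeleton
transform_skeleton <- function(skel, R, tr, s) {
  xyz <- as.matrix(skel[, c("x", "y", "z")]) %*% t(R) * s
  skel$x <- xyz[, 1] + tr[1]
  skel$y <- xyz[, 2] + tr[2]
  skel$z <- xyz[, 3] + tr[3]
  skel
}
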