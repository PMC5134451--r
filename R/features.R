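#' Posture feature names, in canonical order
#'
#' The seven joint-angle features describing one frame's lower-body posture:
#' left/right hip angle, left/right knee angle, left/right ankle angle and the
#' angle between the two leg planes ("two feet angle"). All angles are in
#' radians, in `[0, pi]`.
#'
#' @export
gait_feature_names <- c(
  "left_hip", "right_hip", "left_knee", "right_knee",
  "left_ankle", "right_ankle", "two_feet"
)

# vertex triples for the six included angles (a, vertex b, c)
angle_triples <- list(
  left_hip    = c("HipCenter", "HipLeft",  "KneeLeft"),
  right_hip   = c("HipCenter", "HipRight", "KneeRight"),
  left_knee   = c("HipLeft",   "KneeLeft", "AnkleLeft"),
  right_knee  = c("HipRight",  "KneeRight", "AnkleRight"),
  left_ankle  = c("KneeLeft",  "AnkleLeft", "FootLeft"),
  right_ankle = c("KneeRight", "AnkleRight", "FootRight")
)

#' Included angle at a joint
#'
#' Angle at vertex `b` between the rays `b -> a` and `b -> c`, via the
#' normalized dot product (clamped to `[-1, 1]` before `acos`). Always in
#' `[0, pi]`; invariant under rotation, translation and uniform scaling.
#'
#' @param a,b,c Numeric length-3 points (x, y, z); `b` is the vertex.
#' @return Angle in radians.
#' @export
#' @examples
#' joint_angle(c(0, 1, 0), c(0, 0, 0), c(0, -1, 0)) # pi
#' joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # pi / 2
joint_angle <- function(a, b, c) {
  drop(angle_rows(rbind(a), rbind(b), rbind(c)))
}

# vectorized included angle over row-matched point matrices
angle_rows <- function(a, b, c, tol = 1e-12) {
  u <- a - b
  v <- c - b
  nu <- sqrt(rowSums(u * u))
  nv <- sqrt(rowSums(v * v))
  if (any(nu < tol | nv < tol)) {
    abort(paste0(
      "degenerate geometry: zero-length limb vector at row(s) ",
      paste(which(nu < tol | nv < tol), collapse = ", ")
    ))
  }
  unname(acos(clamp(rowSums(u * v) / (nu * nv), -1, 1)))
}

cross_rows <- function(u, v) {
  cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
}

#' Angle between the two leg planes
#'
#' Each leg's plane is spanned by its hip, knee and ankle joints; the plane
#' normal is `(knee - hip) x (ankle - knee)` (same operand order for both
#' legs) and the feature is the angle between the two normals, in `[0, pi]`.
#' A leg whose three joints are collinear (cross-product norm below `tol`)
#' has no defined plane and raises a degenerate-geometry error; during frame
#' sequence extraction the previous frame's value is substituted instead
#' (see [extract_gait_features()]).
#'
#' @param left_hip,left_knee,left_ankle,right_hip,right_knee,right_ankle
#'   Numeric length-3 points.
#' @param tol Collinearity tolerance on the cross-product norm.
#' @return Angle in radians.
#' @export
two_feet_angle <- function(left_hip, left_knee, left_ankle,
                           right_hip, right_knee, right_ankle,
                           tol = 1e-9) {
  res <- two_feet_rows(
    rbind(left_hip), rbind(left_knee), rbind(left_ankle),
    rbind(right_hip), rbind(right_knee), rbind(right_ankle),
    tol = tol
  )
  if (is.na(res)) {
    abort("degenerate geometry: collinear leg joints, leg plane undefined")
  }
  res
}

# vectorized two-feet angle; returns NA where either leg is collinear
two_feet_rows <- function(lh, lk, la, rh, rk, ra, tol = 1e-9) {
  nl <- cross_rows(lk - lh, la - lk)
  nr <- cross_rows(rk - rh, ra - rk)
  norm_l <- sqrt(rowSums(nl * nl))
  norm_r <- sqrt(rowSums(nr * nr))
  ang <- unname(acos(clamp(rowSums(nl * nr) / (norm_l * norm_r), -1, 1)))
  ang[norm_l < tol | norm_r < tol] <- NA_real_
  ang
}

#' Extract the seven posture features for every frame
#'
#' Computes, per frame, the seven lower-body joint angles that summarise the
#' instantaneous walking posture: hip and knee included angles on each side,
#' ankle included angles (requiring foot joints) and the angle between the two
#' leg planes. Angles are similarity-invariant, so subject height, position
#' and orientation do not affect them.
#'
#' For reduced 15-joint skeletons (no foot joints) the ankle angles are `NA`;
#' the two-feet angle only uses hip/knee/ankle and is still computed unless
#' `sphere_compat = TRUE`, which restricts the output to the hip and knee
#' angles plus the two-feet angle masked as well (the 4-feature OpenNI
#' compatibility mode is not used by default).
#'
#' Frames where a leg is momentarily fully extended (collinear hip-knee-ankle,
#' a normal event in gait) have an undefined leg plane; the previous frame's
#' two-feet angle is carried forward (0 at the first frame) so no `NA` or
#' error escapes for feature 7.
#'
#' @param skeleton A validated skeleton tibble.
#' @param sphere_compat If `TRUE`, mask the two-feet angle (feature 7) in
#'   reduced-joint mode as well, leaving the 4 hip/knee angles.
#' @return A tibble with columns `frame` and the seven features named as in
#'   [gait_feature_names], `NA` for unavailable features.
#' @export
extract_gait_features <- function(skeleton, sphere_compat = FALSE) {
  skeleton <- validate_skeleton(skeleton)
  mode <- joint_mode(skeleton)
  frames <- sort(unique(skeleton$frame))

  J <- function(j) joint_xyz(skeleton, j)
  hip_c <- J("HipCenter")
  hip_l <- J("HipLeft");  hip_r <- J("HipRight")
  knee_l <- J("KneeLeft"); knee_r <- J("KneeRight")
  ank_l <- J("AnkleLeft"); ank_r <- J("AnkleRight")

  out <- tibble::tibble(
    frame = frames,
    left_hip   = angle_rows(hip_c, hip_l, knee_l),
    right_hip  = angle_rows(hip_c, hip_r, knee_r),
    left_knee  = angle_rows(hip_l, knee_l, ank_l),
    right_knee = angle_rows(hip_r, knee_r, ank_r)
  )

  if (mode == "full") {
    foot_l <- J("FootLeft"); foot_r <- J("FootRight")
    out$left_ankle  <- angle_rows(knee_l, ank_l, foot_l)
    out$right_ankle <- angle_rows(knee_r, ank_r, foot_r)
  } else {
    out$left_ankle <- NA_real_
    out$right_ankle <- NA_real_
  }

  if (mode == "reduced" && isTRUE(sphere_compat)) {
    out$two_feet <- NA_real_
  } else {
    tf <- two_feet_rows(hip_l, knee_l, ank_l, hip_r, knee_r, ank_r)
    out$two_feet <- locf(tf, first = 0)
  }
  out[, c("frame", gait_feature_names)]
}

#' Write a posture feature table to CSV
#'
#' Interchange layout `frame,f1,...,f7` with features in canonical order
#' (see [gait_feature_names]); masked features are written as `NA`.
#'
#' @param features A feature tibble from [extract_gait_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  out <- features[, c("frame", gait_feature_names)]
  names(out) <- c("frame", paste0("f", seq_along(gait_feature_names)))
  readr::write_csv(out, path)
  invisible(path)
}
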