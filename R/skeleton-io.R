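#' Canonical skeleton joint names
#'
#' The 20-joint naming of the Kinect v1 SDK skeleton used throughout the
#' package. The 9 lower-body joints drive every feature; reduced 15-joint
#' skeletons (OpenNI-style, no `FootLeft`/`FootRight`) are accepted and
#' flagged, in which case the ankle angles cannot be computed.
#'
#' @format Character vectors of joint names.
#' @name skeleton-joints
NULL

#' @rdname skeleton-joints
#' @export
kinect_joints <- c(
  "HipCenter", "Spine", "ShoulderCenter", "Head",
  "ShoulderLeft", "ElbowLeft", "WristLeft", "HandLeft",
  "ShoulderRight", "ElbowRight", "WristRight", "HandRight",
  "HipLeft", "KneeLeft", "AnkleLeft", "FootLeft",
  "HipRight", "KneeRight", "AnkleRight", "FootRight"
)

#' @rdname skeleton-joints
#' @export
lower_body_joints <- c(
  "HipCenter", "HipLeft", "HipRight", "KneeLeft", "KneeRight",
  "AnkleLeft", "AnkleRight", "FootLeft", "FootRight"
)

foot_joints <- c("FootLeft", "FootRight")

#' Validate a skeleton trajectory table
#'
#' Checks that `skeleton` is a long-format table with columns
#' `frame, joint, x, y, z`, finite coordinates, strictly increasing frame
#' indices, joint names from the canonical 20-joint set, and that every frame
#' carries either the full 9 lower-body joints or the reduced 7-joint set
#' without feet (15-joint skeletons).
#'
#' @param skeleton A data frame with columns `frame, joint, x, y, z`.
#' @return The validated tibble (invisibly usable in pipes), sorted by frame
#'   and canonical joint order, with attributes `joint_mode`
#'   (`"full"` or `"reduced"`) and `fps` (kept if already present, else 30).
#' @export
validate_skeleton <- function(skeleton) {
  needed <- c("frame", "joint", "x", "y", "z")
  if (!all(needed %in% names(skeleton))) {
    abort(paste0(
      "skeleton must have columns ", paste(needed, collapse = ", "),
      "; missing: ", paste(setdiff(needed, names(skeleton)), collapse = ", ")
    ))
  }
  skeleton <- tibble::as_tibble(skeleton)
  bad_joint <- setdiff(unique(skeleton$joint), kinect_joints)
  if (length(bad_joint) > 0L) {
    abort(paste0("unknown joint name(s): ", paste(bad_joint, collapse = ", ")))
  }
  coords <- as.matrix(skeleton[, c("x", "y", "z")])
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    abort("all coordinates must be finite numbers")
  }
  if (any(skeleton$frame < 0) || any(skeleton$frame != round(skeleton$frame))) {
    abort("frame indices must be non-negative integers")
  }

  # full (with feet) or reduced lower-body joint set, identical in every frame
  present <- unique(skeleton$joint)
  mode <- if (all(foot_joints %in% present)) "full" else "reduced"
  required <- if (mode == "full") lower_body_joints else setdiff(lower_body_joints, foot_joints)
  by_frame <- split(skeleton$joint, skeleton$frame)
  for (f in names(by_frame)) {
    miss <- setdiff(required, by_frame[[f]])
    if (length(miss) > 0L) {
      abort(paste0("frame ", f, " is missing required joint(s): ",
                   paste(miss, collapse = ", ")))
    }
    if (anyDuplicated(by_frame[[f]])) {
      abort(paste0("frame ", f, " has duplicated joint rows"))
    }
  }

  skeleton <- dplyr::arrange(
    skeleton,
    .data$frame, match(.data$joint, kinect_joints)
  )
  attr(skeleton, "joint_mode") <- mode
  attr(skeleton, "fps") <- attr(skeleton, "fps") %||% 30
  skeleton
}

#' Joint mode of a skeleton table
#'
#' @param skeleton A validated skeleton tibble.
#' @return `"full"` (20-joint, feet present) or `"reduced"` (15-joint).
#' @export
joint_mode <- function(skeleton) {
  attr(skeleton, "joint_mode") %||%
    (if (all(foot_joints %in% unique(skeleton$joint))) "full" else "reduced")
}

#' Read a skeleton trajectory from CSV
#'
#' Reads the package's long-format interchange layout: a header line
#' `frame,joint,x,y,z` followed by one row per joint per frame, coordinates
#' in meters. Rows may appear in any order within a frame block; frames are
#' grouped and sorted ascending on read.
#'
#' @param path Path to a CSV file.
#' @param fps Frames per second of the recording (default 30, Kinect v1).
#' @return A validated skeleton tibble (see [validate_skeleton()]).
#' @export
read_skeleton_csv <- function(path, fps = 30) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (!is_number(fps) || fps <= 0) abort("fps must be a positive number")
  skel <- readr::read_csv(
    path,
    col_types = readr::cols(
      frame = readr::col_integer(),
      joint = readr::col_character(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double()
    )
  )
  probs <- readr::problems(skel)
  if (nrow(probs) > 0L) {
    abort(paste0(
      "parse error in ", path, " at line(s) ",
      paste(unique(probs$row + 1L), collapse = ", "),
      " (non-numeric or malformed value)"
    ))
  }
  skel <- validate_skeleton(skel)
  attr(skel, "fps") <- fps
  skel
}

#' Write a skeleton trajectory to CSV
#'
#' Writes the long-format layout read by [read_skeleton_csv()], with joints in
#' canonical order within each frame and full double precision (round-trips to
#' well below 1e-9 m).
#'
#' @param skeleton A skeleton tibble (columns `frame, joint, x, y, z`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skeleton_csv <- function(skeleton, path) {
  cols <- c("frame", "joint", "x", "y", "z")
  if (nrow(skeleton) > 0L) skeleton <- validate_skeleton(skeleton)
  out <- tibble::as_tibble(skeleton)[, cols]
  readr::write_csv(out, path)
  invisible(path)
}

# Wide n_frames x 3 coordinate matrix for one joint, rows ordered by frame.
# Assumes a validated skeleton (every frame has the joint).
joint_xyz <- function(skeleton, joint) {
  sub <- skeleton[skeleton$joint == joint, , drop = FALSE]
  sub <- sub[order(sub$frame), , drop = FALSE]
  m <- as.matrix(sub[, c("x", "y", "z")])
  rownames(m) <- sub$frame
  m
}
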