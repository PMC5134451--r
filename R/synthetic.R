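#' Gait types the simulator can produce
#' @export
gait_types <- c("normal", "asymmetric", "stiff_knee", "shuffling", "irregular")

# fixed simulator geometry constants (meters / radians)
HIP_CENTER_RISE <- 0.12   # HipCenter sits this far above the hip line
DORSIFLEX_OFFSET <- 1.3   # fixed foot dorsiflexion from the shin direction
BASELINE_KNEE <- 0.08     # stance-phase knee flexion floor (legs never lock)

#' Simulate a 3D walking skeleton sequence with ground truth
#'
#' A seeded planar (sagittal-plane) kinematic walker: the pelvis translates
#' forward at constant speed; each leg's hip flexion follows
#' `A_h * sin(2*pi*t/T + phi)` and its knee flexion
#' `A_k * max(0, sin(2*pi*t/T + phi + pi/2))` plus a small constant
#' stance-phase flexion, with the left and right legs in anti-phase
#' (`phi_left = 0`, `phi_right = pi`). Joints are placed by two-segment
#' forward kinematics (thigh, shin) hanging from the pelvis, with the foot
#' continuing along the shin direction rotated by a fixed dorsiflexion
#' offset. Gaussian positional noise is added to every joint coordinate
#' last. Upper-body joints are emitted at fixed offsets from the pelvis so
#' the output is a complete 20-joint skeleton.
#'
#' Abnormal gait types perturb the kinematics:
#' * `asymmetric` — one leg's hip and knee amplitudes are scaled by
#'   `asymmetry_ratio` (unequal stride lengths, as when one knee cannot be
#'   loaded);
#' * `stiff_knee` — one knee's amplitude is scaled by `asymmetry_ratio`
#'   (the knee barely flexes);
#' * `shuffling` — both legs' hip and knee amplitudes are scaled by
#'   `asymmetry_ratio` (short, flat-footed strides);
#' * `irregular` — each stride's period is jittered by a factor
#'   `1 + N(0, jitter_sd)`, accumulated continuously (unsteady timing).
#'
#' Ground truth records the analytic (noise-free) per-frame joint angles —
#' both the raw flexions and the included angles the feature extractor should
#' recover — and the frames of the noise-free foot-to-foot distance maxima
#' (cycle boundaries, two per stride since the feet separate at every double
#' support).
#'
#' @param gait_type One of [gait_types].
#' @param n_strides Number of full strides (default 10).
#' @param frames_per_stride Frames per stride period T (default 30).
#' @param fps Frames per second (default 30).
#' @param pelvis_width,thigh,shin,foot_length Segment lengths in meters
#'   (defaults 0.30, 0.45, 0.42, 0.20).
#' @param hip_amplitude,knee_amplitude Flexion amplitudes in radians
#'   (defaults 0.5, 0.9).
#' @param asymmetry_ratio Amplitude scaling in `(0, 1]` for the affected
#'   leg(s) of abnormal types (default 0.5).
#' @param jitter_sd Per-stride timing jitter SD for `irregular` (default 0.1).
#' @param noise_sd Per-coordinate Gaussian noise SD in meters (default 0.005,
#'   typical Kinect v1 joint jitter).
#' @param seed Integer seed; same config and seed give bit-identical output.
#' @return An object of class `gait_simulation`: `skeleton` (a validated
#'   long-format tibble), and `truth` with `boundary_frames`, `angles`
#'   (per-frame tibble of raw flexions and analytic included angles),
#'   `gait_type` and the full `config`.
#' @export
simulate_gait <- function(gait_type = "normal", n_strides = 10,
                          frames_per_stride = 30, fps = 30,
                          pelvis_width = 0.30, thigh = 0.45, shin = 0.42,
                          foot_length = 0.20,
                          hip_amplitude = 0.5, knee_amplitude = 0.9,
                          asymmetry_ratio = 0.5, jitter_sd = 0.1,
                          noise_sd = 0.005, seed = 1) {
  gait_type <- match.arg(gait_type, gait_types)
  if (!is_count(n_strides)) abort("n_strides must be a positive integer")
  if (!is_count(frames_per_stride, min = 4L)) {
    abort("frames_per_stride must be an integer >= 4")
  }
  for (v in c(pelvis_width, thigh, shin, foot_length,
              hip_amplitude, knee_amplitude, fps)) {
    if (!is_number(v) || v <= 0) abort("lengths, amplitudes and fps must be > 0")
  }
  if (!is_number(asymmetry_ratio) || asymmetry_ratio <= 0 || asymmetry_ratio > 1) {
    abort("asymmetry_ratio must be in (0, 1]")
  }
  if (!is_number(noise_sd) || noise_sd < 0) abort("noise_sd must be >= 0")
  if (!is_number(jitter_sd) || jitter_sd < 0) abort("jitter_sd must be >= 0")

  T_ <- frames_per_stride
  n_frames <- n_strides * T_
  frames <- 0:(n_frames - 1L)

  # per-leg amplitudes after the gait-type perturbation (left = affected leg)
  amp <- list(
    hip = c(left = hip_amplitude, right = hip_amplitude),
    knee = c(left = knee_amplitude, right = knee_amplitude)
  )
  if (gait_type == "asymmetric") {
    amp$hip["left"] <- amp$hip["left"] * asymmetry_ratio
    amp$knee["left"] <- amp$knee["left"] * asymmetry_ratio
  } else if (gait_type == "stiff_knee") {
    amp$knee["left"] <- amp$knee["left"] * asymmetry_ratio
  } else if (gait_type == "shuffling") {
    amp$hip <- amp$hip * asymmetry_ratio
    amp$knee <- amp$knee * asymmetry_ratio
  }

  # phase trajectory; irregular gait accumulates jittered stride periods
  phase <- with_seed(derive_seed(seed, 1L), {
    if (gait_type == "irregular" && jitter_sd > 0) {
      fac <- pmax(0.5, 1 + rnorm(n_strides, 0, jitter_sd))
      dphi <- rep(2 * pi / (T_ * fac), each = T_)
      cumsum(c(0, dphi[-n_frames]))
    } else {
      2 * pi * frames / T_
    }
  })

  leg_angles <- function(side) {
    phi <- phase + if (side == "left") 0 else pi
    list(
      hip = amp$hip[side] * sin(phi),
      knee = amp$knee[side] * pmax(0, sin(phi + pi / 2)) + BASELINE_KNEE
    )
  }
  left <- leg_angles("left")
  right <- leg_angles("right")

  # pelvis: forward (z) at a speed consistent with the stride geometry
  speed <- 2 * (thigh + shin) * sin(hip_amplitude) / (T_ / fps)
  hip_y <- thigh + shin + 0.03
  pelvis_z <- speed * frames / fps

  # planar two-segment forward kinematics for one leg (x fixed per side)
  leg_joints <- function(th, tk, side_x, pz) {
    hip <- cbind(x = rep(side_x, n_frames), y = rep(hip_y, n_frames), z = pz)
    knee <- hip + thigh * cbind(0, -cos(th), sin(th))
    psi <- th - tk                       # shin angle from vertical
    ankle <- knee + shin * cbind(0, -cos(psi), sin(psi))
    footdir <- psi + DORSIFLEX_OFFSET
    foot_j <- ankle + foot_length * cbind(0, -cos(footdir), sin(footdir))
    list(hip = hip, knee = knee, ankle = ankle, foot = foot_j)
  }
  lj <- leg_joints(left$hip, left$knee, -pelvis_width / 2, pelvis_z)
  rj <- leg_joints(right$hip, right$knee, pelvis_width / 2, pelvis_z)

  center <- function(dy, dx = 0) {
    cbind(x = rep(dx, n_frames), y = rep(hip_y + dy, n_frames), z = pelvis_z)
  }
  side_pt <- function(dx, dy) center(dy, dx)
  joints <- list(
    HipCenter = center(HIP_CENTER_RISE),
    Spine = center(0.28), ShoulderCenter = center(0.50), Head = center(0.66),
    ShoulderLeft = side_pt(-0.18, 0.46), ElbowLeft = side_pt(-0.21, 0.22),
    WristLeft = side_pt(-0.23, 0.02), HandLeft = side_pt(-0.24, -0.06),
    ShoulderRight = side_pt(0.18, 0.46), ElbowRight = side_pt(0.21, 0.22),
    WristRight = side_pt(0.23, 0.02), HandRight = side_pt(0.24, -0.06),
    HipLeft = lj$hip, KneeLeft = lj$knee, AnkleLeft = lj$ankle,
    FootLeft = lj$foot,
    HipRight = rj$hip, KneeRight = rj$knee, AnkleRight = rj$ankle,
    FootRight = rj$foot
  )

  # analytic ground truth from the noise-free kinematics
  dfoot <- lj$foot - rj$foot
  d <- sqrt(rowSums(dfoot * dfoot))
  interior <- 2:(n_frames - 1L)
  peaks <- interior[d[interior] > d[interior - 1L] & d[interior] > d[interior + 1L]]
  boundary_frames <- frames[peaks]

  # closed-form included angles the feature extractor should reproduce
  hip_included <- function(th) {
    acos(-HIP_CENTER_RISE * cos(th) /
           sqrt((pelvis_width / 2)^2 + HIP_CENTER_RISE^2))
  }
  truth_angles <- tibble::tibble(
    frame = frames,
    theta_hip_left = left$hip, theta_hip_right = right$hip,
    theta_knee_left = left$knee, theta_knee_right = right$knee,
    left_hip = hip_included(left$hip), right_hip = hip_included(right$hip),
    left_knee = pi - left$knee, right_knee = pi - right$knee,
    foot_distance = d
  )

  skel <- tibble::tibble(
    frame = rep(frames, times = length(joints)),
    joint = rep(names(joints), each = n_frames),
    x = unlist(lapply(joints, function(m) m[, 1L]), use.names = FALSE),
    y = unlist(lapply(joints, function(m) m[, 2L]), use.names = FALSE),
    z = unlist(lapply(joints, function(m) m[, 3L]), use.names = FALSE)
  )
  if (noise_sd > 0) {
    noise <- with_seed(derive_seed(seed, 2L),
                       matrix(rnorm(3 * nrow(skel), 0, noise_sd), ncol = 3))
    skel$x <- skel$x + noise[, 1L]
    skel$y <- skel$y + noise[, 2L]
    skel$z <- skel$z + noise[, 3L]
  }
  skel <- validate_skeleton(skel)
  attr(skel, "fps") <- fps

  structure(
    list(
      skeleton = skel,
      truth = list(
        boundary_frames = boundary_frames,
        angles = truth_angles,
        gait_type = gait_type,
        config = list(
          gait_type = gait_type, n_strides = n_strides,
          frames_per_stride = T_, fps = fps,
          pelvis_width = pelvis_width, thigh = thigh, shin = shin,
          foot_length = foot_length, hip_amplitude = hip_amplitude,
          knee_amplitude = knee_amplitude, asymmetry_ratio = asymmetry_ratio,
          jitter_sd = jitter_sd, noise_sd = noise_sd, seed = seed
        )
      )
    ),
    class = "gait_simulation"
  )
}

#' @export
print.gait_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat("<gait_simulation>", cfg$gait_type, "gait:", cfg$n_strides, "strides x",
      cfg$frames_per_stride, "frames,", length(x$truth$boundary_frames),
      "ground-truth cycle boundaries\n")
  invisible(x)
}

#' Write a simulation's ground truth to JSON
#'
#' @param sim A [simulate_gait()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sim, path) {
  stopifnot(inherits(sim, "gait_simulation"))
  obj <- list(
    gait_type = sim$truth$gait_type,
    boundary_frames = as.list(sim$truth$boundary_frames),
    config = sim$truth$config
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
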