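test_that("included angle matches closed-form cases", {
  o <- c(0, 0, 0)
  expect_equal(joint_angle(c(0, 1, 0), o, c(0, -1, 0)), pi)
  expect_equal(joint_angle(c(1, 0, 0), o, c(0, 1, 0)), pi / 2)
  expect_equal(joint_angle(c(1, 0, 0), o, c(1, 1, 0)), pi / 4)
  expect_error(joint_angle(o, o, c(1, 0, 0)), "degenerate")
})

test_that("two-feet angle matches geometric cases and the plane-fit oracle", {
  lh <- c(0, 2, 0); lk <- c(0, 1, 1); la <- c(0, 0, 0)
  # translated copy of the same leg: parallel planes, angle 0
  sh <- c(0.2, 0, 0)
  expect_equal(two_feet_angle(lh, lk, la, lh + sh, lk + sh, la + sh), 0)
  # legs spanning the x=0 and z=0 planes: right angle
  expect_equal(
    two_feet_angle(lh, lk, la, c(0, 2, 0), c(1, 1, 0), c(0, 0, 0)),
    pi / 2
  )
  expect_error(
    two_feet_angle(lh, c(0, 1, 0), la, lh, lk, la),
    "collinear"
  )
  # random non-degenerate legs vs an SVD plane-fit oracle (unoriented)
  withr::local_seed(42)
  for (rep in 1:20) {
    L <- matrix(rnorm(9), 3)
    R <- matrix(rnorm(9), 3)
    got <- two_feet_angle(L[1, ], L[2, ], L[3, ], R[1, ], R[2, ], R[3, ])
    expect_equal(min(got, pi - got), plane_fit_angle(L, R), tolerance = 1e-8)
  }
})

test_that("feature extraction uses the documented joint triples", {
  # straight standing skeleton: knee fully extended -> knee angle pi;
  # two-feet angle degenerate -> carried forward from 0
  straight <- one_frame_skeleton(list(
    KneeLeft = c(-0.15, 0.45, 0), KneeRight = c(0.15, 0.45, 0),
    AnkleLeft = c(-0.15, 0.05, 0), AnkleRight = c(0.15, 0.05, 0),
    FootLeft = c(-0.15, 0.05, 0.2), FootRight = c(0.15, 0.05, 0.2)
  ))
  f <- extract_gait_features(straight)
  expect_equal(f$left_knee, pi)
  expect_equal(f$right_knee, pi)
  expect_equal(f$two_feet, 0)
  expect_equal(f$left_ankle, pi / 2)
})

test_that("features are invariant under similarity transforms", {
  withr::local_seed(3)
  sim <- simulate_gait("normal", n_strides = 2, seed = 5)
  skel <- sim$skeleton
  ref <- extract_gait_features(skel)
  for (rep in 1:3) {
    moved <- transform_skeleton(skel, random_rotation(),
                                rnorm(3, 0, 5), runif(1, 0.5, 2))
    got <- extract_gait_features(moved)
    expect_lt(max(abs(as.matrix(got[, -1]) - as.matrix(ref[, -1]))), 1e-9)
  }
})

test_that("extracted hip and knee angles match the simulator's closed forms", {
  sim <- simulate_gait("normal", n_strides = 3, noise_sd = 0, seed = 9)
  f <- extract_gait_features(sim$skeleton)
  truth <- sim$truth$angles
  for (col in c("left_hip", "right_hip", "left_knee", "right_knee")) {
    expect_lt(max(abs(f[[col]] - truth[[col]])), 1e-6)
  }
})

test_that("all features stay in [0, pi] and never go NaN on noisy input", {
  sim <- simulate_gait("shuffling", n_strides = 4, noise_sd = 0.01, seed = 2)
  f <- as.matrix(extract_gait_features(sim$skeleton)[, -1])
  expect_true(all(is.finite(f)))
  expect_true(all(f >= 0 & f <= pi))
})

test_that("reduced 15-joint skeletons mask the ankle angles", {
  sim <- simulate_gait("normal", n_strides = 2, seed = 4)
  reduced <- dplyr::filter(sim$skeleton,
                           !joint %in% c("FootLeft", "FootRight"))
  f <- extract_gait_features(reduced)
  expect_true(all(is.na(f$left_ankle)))
  expect_true(all(is.na(f$right_ankle)))
  expect_true(all(is.finite(f$two_feet)))
  f2 <- extract_gait_features(reduced, sphere_compat = TRUE)
  expect_true(all(is.na(f2$two_feet)))
  expect_true(all(is.finite(f2$left_knee)))
})
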