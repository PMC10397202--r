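test_that("static trajectories have zero speeds and exact distances", {
  pose <- fixture_pose()
  pose["nose", ] <- c(40, 0, 0)
  pose["root_tail", ] <- c(0, 0, 0)
  tr <- fixture_traj(pose, T = 6)
  f <- compute_pose_features(tr, c("length", "back_speed", "nose_speed",
                                   "acceleration", "body_speed"))
  expect_equal(f$length, rep(40, 6))
  expect_equal(f$back_speed, rep(0, 5))
  expect_equal(f$nose_speed, rep(0, 5))
  expect_equal(f$acceleration, rep(0, 4))
  expect_equal(f$body_speed, rep(0, 5))
  expect_error(compute_pose_features(tr, "wingspan"), "unknown")
})

test_that("spine angle matches hand-computed vector geometry", {
  pose <- fixture_pose()
  # collinear: neck ahead of back, tail root behind -> angle pi
  pose["neck", ] <- c(30, 0, 10)
  pose["back", ] <- c(0, 0, 10)
  pose["root_tail", ] <- c(-30, 0, 10)
  tr <- fixture_traj(pose, T = 3)
  expect_equal(compute_pose_features(tr, "spine_angle")$spine_angle,
               rep(pi, 3))
  # right angle at the back
  pose["root_tail", ] <- c(0, -30, 10)
  tr <- fixture_traj(pose, T = 3)
  expect_equal(compute_pose_features(tr, "spine_angle")$spine_angle,
               rep(pi / 2, 3))
})

test_that("angular velocity tracks the deflection of the body axis", {
  pose1 <- fixture_pose()
  pose1["root_tail", ] <- c(0, 0, 10); pose1["neck", ] <- c(30, 0, 10)
  pose2 <- pose1
  pose2["neck", ] <- c(0, 30, 10)   # axis rotated 90 degrees
  tr <- fixture_traj(list(pose1, pose2), frame_rate = 30)
  expect_equal(compute_pose_features(tr, "angular_velocity")$angular_velocity,
               pi / 2)
})

test_that("distances, angles and speeds are rigid-motion invariant", {
  tr <- generate_skeleton(kinematic_profile("Hyper"), open_field_arena(),
                          200, seed = 8)
  moved <- transform_traj(tr, shift = c(150, -80, 0), angle = 0.83)
  inv_feats <- c("length", "front_width", "hind_width", "back_speed",
                 "nose_speed", "acceleration", "angular_velocity",
                 "spine_angle", "body_speed")
  a <- compute_pose_features(tr, inv_feats)
  b <- compute_pose_features(moved, inv_feats)
  for (f in inv_feats) expect_equal(a[[f]], b[[f]], tolerance = 1e-8)

  # heights are invariant to planar translation only
  planar <- transform_traj(tr, shift = c(50, 60, 0))
  lifted <- transform_traj(tr, shift = c(0, 0, 10))
  expect_equal(compute_pose_features(planar, "back_height")$back_height,
               compute_pose_features(tr, "back_height")$back_height)
  expect_equal(compute_pose_features(lifted, "neck_height")$neck_height,
               compute_pose_features(tr, "neck_height")$neck_height + 10)
})

test_that("pmf counts and normalises like a direct histogram", {
  set.seed(1)
  u <- stats::runif(100)
  cu <- pmf(u, bins = 50)
  expect_equal(sum(cu$probabilities), 1)
  expect_equal(length(cu$bin_edges), 51)

  m <- c(rep(1, 30), rep(9, 70))
  cm <- pmf(m, bins = 50)
  occupied <- which(cm$probabilities > 0)
  expect_equal(length(occupied), 2)
  expect_equal(unname(cm$probabilities[occupied]), c(0.3, 0.7))

  cc <- pmf(rep(3.5, 10))
  expect_equal(max(cc$probabilities), 1)
  expect_equal(sum(cc$probabilities > 0), 1)
  expect_error(pmf(1), "2 finite")
})

test_that("PMF descriptors follow their definitions and ordering", {
  uniform <- pmf(stats::qunif(seq(0.001, 0.999, length.out = 5000)), 50)
  s <- summarize_pmf(uniform)
  expect_equal(names(s), c("mean", "median", "sd", "q25", "q75", "min",
                           "max"))
  expect_equal(unname(s["mean"]), 0.02)

  onehot <- pmf(rep(1, 10))
  s1 <- summarize_pmf(onehot)
  expect_equal(unname(s1[c("mean", "min", "max")]), c(0.02, 0, 1))

  # order statistics are ordered for arbitrary curves
  set.seed(2)
  for (i in 1:5) {
    s2 <- summarize_pmf(pmf(stats::rgamma(500, shape = 2)))
    expect_true(s2["min"] <= s2["q25"] && s2["q25"] <= s2["median"] &&
                s2["median"] <= s2["q75"] && s2["q75"] <= s2["max"])
  }

  # distribution-level variant recovers the underlying location
  sv <- summarize_pmf(pmf(stats::rnorm(20000, mean = 7, sd = 0.5)),
                      on = "values")
  expect_equal(unname(sv["mean"]), 7, tolerance = 0.05)
})

test_that("summary vector length follows the feature configuration", {
  tr <- generate_skeleton(kinematic_profile("Hypo"), open_field_arena(),
                          500, seed = 4)
  expect_length(eigenvalue_vector(tr), 91)
  expect_length(eigenvalue_vector(tr, pose_feature_set("reduced11")), 77)
  expect_length(eigenvalue_vector(tr, "back_speed"), 7)
  ev <- eigenvalue_vector(tr)
  expect_identical(ev, eigenvalue_vector(tr))  # deterministic
  expect_equal(names(ev)[1:7],
               paste("length", c("mean", "median", "sd", "q25", "q75",
                                 "min", "max"), sep = "."))
})
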