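test_that("label generator honours degenerate and deterministic cases", {
  point_mass <- c(rep(0, 11), 1, rep(0, 28))
  ml <- generate_labels(point_mass, 500, seed = 1)
  expect_true(all(ml$labels == 12L))

  p <- group_profile("control-like")
  expect_identical(generate_labels(p, 1000, seed = 9)$labels,
                   generate_labels(p, 1000, seed = 9)$labels)
  expect_error(generate_labels(p, 0, seed = 1), "n_frames")
})

test_that("empirical fractions converge to the profile fractions", {
  p <- group_profile("control-like")
  fr <- movement_fractions(generate_labels(p, 200000, seed = 7))
  expect_lt(max(abs(fr - 0.025)), 0.005)
})

test_that("POD-like profiles shift exactly the designated movements", {
  ctrl <- group_profile("control-like")
  podp <- group_profile("POD-like")
  dm <- discriminative_movements()
  delta <- podp$fraction_means - ctrl$fraction_means
  expect_true(all(delta[dm$up] > 0))
  expect_true(all(delta[dm$down] < 0))
  expect_true(all(delta[-c(dm$up, dm$down)] == 0))
  expect_equal(sum(podp$fraction_means), 1, tolerance = 1e-9)
})

test_that("skeleton generator respects arena bounds and speed scaling", {
  arena <- open_field_arena()
  hyper <- generate_skeleton(kinematic_profile("Hyper"), arena, 10000,
                             seed = 1)
  hypo <- generate_skeleton(kinematic_profile("Hypo"), arena, 10000,
                            seed = 2)
  med_speed <- function(tr)
    stats::median(compute_pose_features(tr, "back_speed")$back_speed)
  expect_gt(med_speed(hyper), med_speed(hypo))

  still <- generate_skeleton(kinematic_profile("Hyper", speed_scale = 0),
                             arena, 2000, seed = 3)
  expect_lt(med_speed(still), 3)  # keypoint noise only (~1 mm per axis)

  xy <- keypoint(hyper, "back")[, 1:2]
  expect_true(all(sqrt(rowSums(xy^2)) < arena$size / 2))
  expect_error(generate_skeleton(kinematic_profile("Hyper"),
                                 arena_spec("circle", size = 150), 100,
                                 seed = 1),
               "too small")
})

test_that("height scale moves nose, neck and back heights together", {
  arena <- open_field_arena()
  hi <- generate_skeleton(kinematic_profile("Hyper", height_scale = 30),
                          arena, 3000, seed = 4)
  lo <- generate_skeleton(kinematic_profile("Hyper", height_scale = 20),
                          arena, 3000, seed = 4)
  for (kp in c("nose", "neck", "back"))
    expect_gt(stats::median(keypoint(hi, kp)[, 3]),
              stats::median(keypoint(lo, kp)[, 3]))
})

test_that("scheduled investigation sessions satisfy their geometric contract", {
  arena <- nor_arena()
  kin <- kinematic_profile("Hyper")
  sched <- investigation_schedule(start = c(201, 601), end = c(290, 690),
                                  role = c("novel", "familiar"),
                                  depth = c("deep", "shallow"),
                                  n_frames = 900)
  tr <- generate_investigation_session(sched, arena, kin, seed = 5)
  expect_equal(n_frames(tr), 900)

  nose <- keypoint(tr, "nose")
  in_bout <- logical(900)
  for (i in 1:2) in_bout[sched$start[i]:sched$end[i]] <- TRUE
  d_min <- pmin(
    sqrt((nose[, 1] - 100)^2 + (nose[, 2] - 80)^2),
    sqrt((nose[, 1] - 300)^2 + (nose[, 2] - 80)^2))
  expect_true(all(d_min[!in_bout] > 80))
  expect_true(all(d_min[in_bout] < 60))

  # the deep bout must contain climbing frames (back above the object top)
  back_z <- keypoint(tr, "back")[, 3]
  expect_true(any(back_z[sched$start[1]:sched$end[1]] >
                  arena$objects[[1]]$top_height))

  # empty schedule: no investigation anywhere
  empty <- investigation_schedule(integer(0), integer(0), character(0),
                                  character(0), n_frames = 600)
  tr0 <- generate_investigation_session(empty, arena, kin, seed = 6)
  rec0 <- investigation_record(tr0, arena)
  expect_equal(nrow(rec0$bouts), 0)

  expect_error(investigation_schedule(c(1, 50), c(60, 100),
                                      c("novel", "novel"),
                                      c("deep", "deep"), 200),
               "separated")
})

test_that("generators are pure functions of parameters and seed", {
  arena <- open_field_arena()
  kin <- kinematic_profile("Hypo")
  a <- generate_skeleton(kin, arena, 300, seed = 11)
  b <- generate_skeleton(kin, arena, 300, seed = 11)
  expect_identical(a$frames, b$frames)
})
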