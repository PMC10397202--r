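test_that("DSP follows the arcsine formula with its closed-form anchors", {
  expect_equal(dsp(3, 0), pi / 2)
  expect_equal(dsp(0, 3), -pi / 2)
  expect_equal(dsp(4, 4), 0)
  expect_equal(dsp(3, 1), asin(0.5))
  expect_error(dsp(0, 0), "undefined")
})

test_that("DSP is antisymmetric and monotone in deep time", {
  set.seed(6)
  for (i in 1:20) {
    a <- stats::runif(1, 0, 30); b <- stats::runif(1, 0, 30)
    expect_equal(dsp(a, b), -dsp(b, a))
  }
  grid <- seq(0.5, 20, length.out = 15)
  vals <- vapply(grid, dsp, 0, t_shallow = 5)
  expect_true(all(diff(vals) > 0))
})

test_that("approach rule requires proximity and facing", {
  obj <- object_spec(c(0, 0), top_height = 60)
  # nose 50 mm from the object, neck behind it, pointing straight at it
  pose <- fixture_pose()
  pose["nose", ] <- c(50, 0, 20)
  pose["neck", ] <- c(75, 0, 25)
  pose["back", ] <- c(105, 0, 25)
  tr <- fixture_traj(pose, T = 10)
  det <- detect_investigation(tr, obj)
  expect_true(all(det$mask))
  expect_equal(det$bouts$trigger, "approach")

  # same geometry but facing away: nose farther than neck
  pose2 <- fixture_pose()
  pose2["nose", ] <- c(100, 0, 20)
  pose2["neck", ] <- c(75, 0, 25)
  pose2["back", ] <- c(45, 0, 25)
  pose2[, 1] <- pose2[, 1] - 50      # nose now 50 mm away, pointing away
  det2 <- detect_investigation(fixture_traj(pose2, T = 10), obj)
  expect_false(any(det2$mask))

  # out of range entirely
  pose3 <- fixture_pose()
  pose3[, 1] <- pose3[, 1] + 100
  det3 <- detect_investigation(fixture_traj(pose3, T = 10), obj)
  expect_false(any(det3$mask))
})

test_that("climb rule ignores orientation but needs height", {
  obj <- object_spec(c(0, 0), top_height = 60)
  # nose 25 mm away but facing away; back above the object top
  pose <- fixture_pose()
  pose["nose", ] <- c(25, 0, 40)
  pose["neck", ] <- c(5, 0, 65)
  pose["back", ] <- c(-20, 0, 70)
  tr <- fixture_traj(pose, T = 8)
  det <- detect_investigation(tr, obj)
  expect_true(all(det$mask))
  expect_equal(det$bouts$trigger, "climb")

  # same but back below the top: neither rule fires
  pose["back", 3] <- 30
  pose["neck", 3] <- 28
  det2 <- detect_investigation(fixture_traj(pose, T = 8), obj)
  expect_false(any(det2$mask))
})

test_that("bout merging joins runs separated by short gaps", {
  obj <- object_spec(c(0, 0), top_height = 60)
  near <- fixture_pose()
  near["nose", ] <- c(50, 0, 20); near["neck", ] <- c(75, 0, 25)
  far <- fixture_pose(); far[, 1] <- far[, 1] + 200
  poses <- c(replicate(10, near, simplify = FALSE),
             replicate(3, far, simplify = FALSE),
             replicate(10, near, simplify = FALSE))
  det <- detect_investigation(fixture_traj(poses), obj)
  expect_equal(nrow(det$bouts), 1)
  poses2 <- c(replicate(10, near, simplify = FALSE),
              replicate(8, far, simplify = FALSE),
              replicate(10, near, simplify = FALSE))
  det2 <- detect_investigation(fixture_traj(poses2), obj)
  expect_equal(nrow(det2$bouts), 2)
})

test_that("depth classification: climb precedence, then deep labels", {
  bouts <- data.frame(start = c(1L, 11L, 21L), end = c(10L, 20L, 30L),
                      trigger = c("climb", "approach", "approach"))
  labels <- movement_labels(c(rep(1L, 15), rep(35L, 5), rep(1L, 10)))
  out <- classify_bouts(bouts, labels, deep_classes = 35L)
  expect_equal(out$depth, c("deep", "deep", "shallow"))
  out2 <- classify_bouts(bouts, labels, deep_classes = integer(0))
  expect_equal(out2$depth, c("deep", "shallow", "shallow"))
})

test_that("scheduled sessions are recovered bout-for-bout", {
  arena <- nor_arena()
  sched <- investigation_schedule(start = c(151, 451), end = c(240, 540),
                                  role = c("novel", "familiar"),
                                  depth = c("deep", "shallow"),
                                  n_frames = 700)
  tr <- generate_investigation_session(sched, arena,
                                       kinematic_profile("Hypo"), seed = 21)
  rec <- investigation_record(tr, arena)
  b <- rec$bouts[order(rec$bouts$start), ]
  expect_equal(nrow(b), 2)
  expect_equal(b$start, sched$start)
  expect_equal(b$end, sched$end)
  expect_equal(b$depth, sched$depth)
  expect_equal(b$role, sched$role)
  expect_equal(rec$t_deep, 3)     # 90 frames at 30 fps
  expect_equal(rec$t_shallow, 3)
  expect_equal(rec$dsp, 0)
})
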