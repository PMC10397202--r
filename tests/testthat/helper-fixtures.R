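# Fixture builders shared across the test files. Everything is generated in
# code; no data files.

# A single static pose: named 16 x 3 coordinate matrix (mm) in a roughly
# anatomical layout, nose pointing along +x.
fixture_pose <- function() {
  m <- rbind(
    nose             = c( 55,   0, 20),
    left_ear         = c( 45,  10, 25),
    right_ear        = c( 45, -10, 25),
    neck             = c( 30,   0, 28),
    left_front_limb  = c( 20,  12,  8),
    right_front_limb = c( 20, -12,  8),
    left_hind_limb   = c( -5,  14,  8),
    right_hind_limb  = c( -5, -14,  8),
    left_front_claw  = c( 25,  14,  2),
    right_front_claw = c( 25, -14,  2),
    left_hind_claw   = c( -2,  16,  2),
    right_hind_claw  = c( -2, -16,  2),
    back             = c(  0,   0, 25),
    root_tail        = c(-30,   0, 15),
    middle_tail      = c(-55,   0,  9),
    tail_tip         = c(-80,   0,  5))
  m[keypoint_names(), , drop = FALSE]
}

# Replicate a pose (or a list of per-frame poses) into a trajectory.
fixture_traj <- function(pose = fixture_pose(), T = 5, frame_rate = 30) {
  if (is.matrix(pose)) pose <- replicate(T, pose, simplify = FALSE)
  fr <- array(0, c(length(pose), 16, 3))
  for (t in seq_along(pose)) fr[t, , ] <- pose[[t]]
  skeleton_trajectory(fr, frame_rate = frame_rate)
}

# Translate and/or rotate (about z) a whole trajectory.
transform_traj <- function(traj, shift = c(0, 0, 0), angle = 0) {
  fr <- traj$frames
  ca <- cos(angle); sa <- sin(angle)
  x <- fr[, , 1] * ca - fr[, , 2] * sa
  y <- fr[, , 1] * sa + fr[, , 2] * ca
  fr[, , 1] <- x + shift[1]
  fr[, , 2] <- y + shift[2]
  fr[, , 3] <- fr[, , 3] + shift[3]
  skeleton_trajectory(fr, frame_rate = traj$frame_rate)
}

# Adjusted Rand index between two labelings (independent oracle from mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Six well-separated scheduled bouts (3 deep, 3 shallow) used by the
# investigation recovery checks.
fixture_schedule <- function() {
  investigation_schedule(
    start = c(301, 901, 1501, 2101, 2701, 3301),
    end   = c(420, 1020, 1620, 2220, 2820, 3420),
    role  = rep(c("familiar", "novel"), 3),
    depth = rep(c("deep", "shallow"), each = 3),
    n_frames = 3900)
}
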