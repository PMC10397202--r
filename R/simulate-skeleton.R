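# Nominal body plan: per-keypoint (forward, lateral) offsets in mm relative
# to the back, and height factors relative to height_scale (back = 1).
.body_plan <- function() {
  plan <- rbind(
    nose             = c( 55,   0, 0.80),
    left_ear         = c( 45,  10, 1.00),
    right_ear        = c( 45, -10, 1.00),
    neck             = c( 30,   0, 1.10),
    left_front_limb  = c( 20,  12, 0.30),
    right_front_limb = c( 20, -12, 0.30),
    left_hind_limb   = c( -5,  14, 0.30),
    right_hind_limb  = c( -5, -14, 0.30),
    left_front_claw  = c( 25,  14, 0.08),
    right_front_claw = c( 25, -14, 0.08),
    left_hind_claw   = c( -2,  16, 0.08),
    right_hind_claw  = c( -2, -16, 0.08),
    back             = c(  0,   0, 1.00),
    root_tail        = c(-30,   0, 0.60),
    middle_tail      = c(-55,   0, 0.35),
    tail_tip         = c(-80,   0, 0.20))
  colnames(plan) <- c("fwd", "lat", "zf")
  plan[keypoint_names(), , drop = FALSE]
}

# Largest planar body-plan offset; used for wall margins.
.body_extent <- function() max(abs(.body_plan()[, c("fwd", "lat")]))

# Assemble a 16-keypoint trajectory from a back-keypoint path, per-frame
# heading, per-frame height scale, and isotropic keypoint noise.
.assemble_skeleton <- function(back_xy, heading, height_scale, frame_rate = 30,
                               noise_sd = 1) {
  T <- nrow(back_xy)
  plan <- .body_plan()
  if (length(height_scale) == 1L) height_scale <- rep(height_scale, T)
  fr <- array(0, c(T, 16L, 3L))
  ch <- cos(heading); sh <- sin(heading)
  for (k in 1:16) {
    fwd <- plan[k, "fwd"]; lat <- plan[k, "lat"]
    fr[, k, 1] <- back_xy[, 1] + fwd * ch - lat * sh
    fr[, k, 2] <- back_xy[, 2] + fwd * sh + lat * ch
    fr[, k, 3] <- plan[k, "zf"] * height_scale
  }
  fr <- fr + stats::rnorm(length(fr), sd = noise_sd)
  fr[, , 3][fr[, , 3] < 0] <- 0
  skeleton_trajectory(fr, frame_rate = frame_rate)
}

# Reflect a point into the feasible region of the arena (margin mm inside the
# walls). Returns the reflected coordinates.
.reflect_into <- function(xy, arena, margin) {
  if (arena$shape == "circle") {
    rmax <- arena$size / 2 - margin
    r <- sqrt(sum(xy^2))
    if (r > rmax && r > 0) xy <- xy * (2 * rmax - r) / r
    xy
  } else {
    lo <- margin; hi <- arena$size - margin
    for (a in 1:2) {
      if (xy[a] < lo) xy[a] <- 2 * lo - xy[a]
      if (xy[a] > hi) xy[a] <- 2 * hi - xy[a]
      xy[a] <- min(max(xy[a], lo), hi)  # guard against double overshoot
    }
    xy
  }
}

#' Generate a synthetic skeleton trajectory
#'
#' The body centroid (the back keypoint) follows a smoothed
#' Ornstein-Uhlenbeck random walk reflected at the arena walls; heading
#' follows the direction of travel with diffusion `turn_rate`; the remaining
#' keypoints are heading-rotated body-plan offsets around the back with
#' isotropic 1 mm noise. The median per-frame back displacement scales with
#' `kin$speed_scale`, and nose/neck/back heights track `kin$height_scale`.
#'
#' @param kin a [kinematic_profile()].
#' @param arena an [arena_spec()].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param frame_rate frames per second.
#' @return A [skeleton_trajectory()].
#' @export
generate_skeleton <- function(kin, arena, n_frames, seed, frame_rate = 30) {
  stopifnot(inherits(kin, "kinematic_profile"), inherits(arena, "arena_spec"))
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  margin <- .body_extent() + 5
  free <- if (arena$shape == "circle") arena$size / 2 - margin
          else arena$size / 2 - margin
  if (free < 20) stop("arena too small for the body plan", call. = FALSE)
  set.seed(seed)
  rho <- 0.9
  # per-component OU stationary SD chosen so the Rayleigh median of |v|
  # equals speed_scale
  sv <- kin$speed_scale / sqrt(2 * log(2))
  v <- matrix(0, n_frames, 2)
  xy <- matrix(0, n_frames, 2)
  xy[1, ] <- arena_centre(arena)
  v[1, ] <- stats::rnorm(2, sd = sv)
  eps <- matrix(stats::rnorm(2 * n_frames, sd = sv * sqrt(1 - rho^2)),
                n_frames, 2)
  for (t in 2:n_frames) {
    v[t, ] <- rho * v[t - 1, ] + eps[t, ]
    cand <- xy[t - 1, ] + v[t, ]
    refl <- .reflect_into(cand, arena, margin)
    if (any(refl != cand)) v[t, ] <- refl - xy[t - 1, ]
    xy[t, ] <- refl
  }
  # heading: turns toward the direction of travel at a bounded angular rate
  # (turn_rate rad/frame); diffuses gently when the animal is near-still
  heading <- numeric(n_frames)
  heading[1] <- stats::runif(1, -pi, pi)
  turn <- stats::rnorm(n_frames, sd = kin$turn_rate / 3)
  wrap <- function(a) atan2(sin(a), cos(a))
  for (t in 2:n_frames) {
    sp <- sqrt(sum(v[t, ]^2))
    if (sp > 0.5) {
      delta <- wrap(atan2(v[t, 2], v[t, 1]) - heading[t - 1])
      heading[t] <- heading[t - 1] + sign(delta) * min(abs(delta),
                                                       kin$turn_rate)
    } else heading[t] <- heading[t - 1] + turn[t]
  }
  .assemble_skeleton(xy, heading, kin$height_scale, frame_rate = frame_rate)
}
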