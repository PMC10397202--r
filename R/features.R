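# Euclidean norm of matrix rows
.rownorm <- function(m) sqrt(rowSums(m^2))

# Per-frame 3-D displacement of a T x 3 coordinate matrix (length T-1)
.displacement <- function(m) .rownorm(diff(m))

# Angle between corresponding rows of two T x 3 matrices, in [0, pi]
.row_angle <- function(a, b) {
  cosang <- rowSums(a * b) / (.rownorm(a) * .rownorm(b))
  acos(pmin(1, pmax(-1, cosang)))
}

#' Pose feature sets
#'
#' The full configuration has 13 features: the enumerated pose descriptors
#' (with height split into neck and back height) plus the whole-body
#' centroid speed. The reduced 11-feature configuration keeps a single
#' (back) height and drops the centroid speed; with 7 descriptor statistics
#' per feature these yield 91- and 77-dimensional summary vectors
#' respectively.
#'
#' @param which `"full13"` or `"reduced11"`.
#' @return Character vector of feature names.
#' @export
pose_feature_set <- function(which = c("full13", "reduced11")) {
  which <- match.arg(which)
  base <- c("length", "back_height", "front_width", "hind_width",
            "back_speed", "nose_speed", "left_front_claw_speed",
            "right_front_claw_speed", "acceleration", "angular_velocity",
            "spine_angle")
  if (which == "reduced11") base
  else c(base[1], "neck_height", base[-1], "body_speed")
}

#' Compute per-frame pose features from a skeleton trajectory
#'
#' Distances and widths are 3-D point-to-point distances (mm); heights are
#' the z coordinate of the named keypoint (mm); speeds are per-frame 3-D
#' displacements (mm/frame); acceleration is the first difference of back
#' speed (mm/frame^2); angular velocity is the per-frame deflection of the
#' tail-root-to-neck axis (rad/frame); spine angle is the angle at the back
#' between the back-to-neck and back-to-tail-root vectors (rad). Differenced
#' features are one (or two) frames shorter than the trajectory.
#'
#' @param traj a [skeleton_trajectory()].
#' @param feature_list character vector of feature names (default the full
#'   13-feature configuration, [pose_feature_set()]).
#' @return Named list of numeric vectors, one per requested feature.
#' @export
compute_pose_features <- function(traj, feature_list = pose_feature_set()) {
  stopifnot(inherits(traj, "skeleton_trajectory"))
  known <- pose_feature_set("full13")
  bad <- setdiff(feature_list, known)
  if (length(bad))
    stop("unknown pose feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  kp <- function(n) keypoint(traj, n)
  out <- list()
  for (f in feature_list) {
    out[[f]] <- switch(f,
      length = .rownorm(kp("nose") - kp("root_tail")),
      neck_height = kp("neck")[, 3],
      back_height = kp("back")[, 3],
      front_width = .rownorm(kp("left_front_limb") - kp("right_front_limb")),
      hind_width = .rownorm(kp("left_hind_limb") - kp("right_hind_limb")),
      back_speed = .displacement(kp("back")),
      nose_speed = .displacement(kp("nose")),
      left_front_claw_speed = .displacement(kp("left_front_claw")),
      right_front_claw_speed = .displacement(kp("right_front_claw")),
      acceleration = diff(.displacement(kp("back"))),
      angular_velocity = {
        axis <- kp("neck") - kp("root_tail")
        .row_angle(axis[-nrow(axis), , drop = FALSE],
                   axis[-1, , drop = FALSE])
      },
      spine_angle = .row_angle(kp("neck") - kp("back"),
                               kp("root_tail") - kp("back")),
      body_speed = {
        centroid <- apply(traj$frames, c(1, 3), mean)
        .displacement(centroid)
      })
  }
  out
}

#' Convert per-frame speeds from mm/frame to mm/s
#'
#' Reporting convenience: multiplies speed-type features by the frame rate.
#'
#' @param values numeric vector in mm/frame (or mm/frame^2).
#' @param frame_rate frames per second.
#' @param order differencing order (1 for speeds, 2 for acceleration).
#' @return Numeric vector in mm/s (or mm/s^2).
#' @export
per_second <- function(values, frame_rate, order = 1) values * frame_rate^order
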