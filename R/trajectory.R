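#' Canonical keypoint names
#'
#' The 16 tracked body parts, in the canonical order used throughout the
#' package: all trajectories are stored as `T x 16 x 3` arrays with the third
#' margin being x, y, z in millimetres.
#'
#' @return Character vector of length 16.
#' @export
keypoint_names <- function() {
  c("nose", "left_ear", "right_ear", "neck",
    "left_front_limb", "right_front_limb",
    "left_hind_limb", "right_hind_limb",
    "left_front_claw", "right_front_claw",
    "left_hind_claw", "right_hind_claw",
    "back", "root_tail", "middle_tail", "tail_tip")
}

#' Construct a skeleton trajectory
#'
#' @param frames numeric `T x 16 x 3` array of keypoint coordinates (mm),
#'   keypoints in [keypoint_names()] order.
#' @param frame_rate frames per second (default 30, the acquisition rate of
#'   the multi-view capture system this package targets).
#' @return An object of class `skeleton_trajectory`.
#' @export
skeleton_trajectory <- function(frames, frame_rate = 30) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x 16 x 3 array", call. = FALSE)
  d <- dim(frames)
  if (d[2] != 16L || d[3] != 3L)
    stop("`frames` must have dimensions T x 16 x 3, got ",
         paste(d, collapse = " x "), call. = FALSE)
  if (d[1] < 2L)
    stop("a trajectory needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(frames))) {
    bad <- which(!is.finite(frames), arr.ind = TRUE)
    stop("non-finite coordinate at frame ", bad[1, 1],
         " (keypoint '", keypoint_names()[bad[1, 2]], "')", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  dimnames(frames) <- list(NULL, keypoint_names(), c("x", "y", "z"))
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "skeleton_trajectory")
}

#' @export
print.skeleton_trajectory <- function(x, ...) {
  cat("Skeleton trajectory: ", n_frames(x), " frames x 16 keypoints, ",
      x$frame_rate, " fps (", round(n_frames(x) / x$frame_rate, 1),
      " s)\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [skeleton_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one keypoint's coordinate matrix
#' @param traj a [skeleton_trajectory()].
#' @param name a canonical keypoint name.
#' @return `T x 3` matrix.
#' @export
keypoint <- function(traj, name) {
  if (!name %in% keypoint_names())
    stop("unknown keypoint '", name, "'", call. = FALSE)
  traj$frames[, name, , drop = TRUE]
}

#' Read a skeleton trajectory from CSV
#'
#' The canonical dialect is a comma-delimited table with a header: a `frame`
#' column (1-based) followed by `<keypoint>_x`, `<keypoint>_y`, `<keypoint>_z`
#' columns for each of the 16 canonical keypoints, coordinates in mm. Column
#' order in the file is irrelevant; `keypoint_map` renames foreign headers
#' (e.g. `c(snout = "nose")` maps columns `snout_x` etc. onto `nose`).
#'
#' @param path file path.
#' @param frame_rate frames per second of the recording.
#' @param keypoint_map optional named character vector, foreign name ->
#'   canonical name.
#' @return A [skeleton_trajectory()].
#' @export
read_trajectory <- function(path, frame_rate = 30, keypoint_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(keypoint_map)) {
    for (from in names(keypoint_map)) {
      for (ax in c("x", "y", "z")) {
        i <- match(paste0(from, "_", ax), names(df))
        if (!is.na(i)) names(df)[i] <- paste0(keypoint_map[[from]], "_", ax)
      }
    }
  }
  kp <- keypoint_names()
  need <- as.vector(outer(kp, c("x", "y", "z"), paste, sep = "_"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    miss_kp <- unique(sub("_[xyz]$", "", missing_cols))
    stop("trajectory file is missing columns for keypoint(s): ",
         paste(miss_kp, collapse = ", "), call. = FALSE)
  }
  T <- nrow(df)
  fr <- array(NA_real_, c(T, 16L, 3L))
  for (k in seq_along(kp))
    for (a in 1:3)
      fr[, k, a] <- df[[paste0(kp[k], "_", c("x", "y", "z")[a])]]
  skeleton_trajectory(fr, frame_rate = frame_rate)
}

#' Write a skeleton trajectory to CSV
#'
#' Emits the canonical dialect accepted by [read_trajectory()]: a `frame`
#' column plus 48 coordinate columns.
#'
#' @param traj a [skeleton_trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "skeleton_trajectory"))
  kp <- keypoint_names()
  out <- data.frame(frame = seq_len(n_frames(traj)))
  for (k in seq_along(kp))
    for (a in 1:3)
      out[[paste0(kp[k], "_", c("x", "y", "z")[a])]] <- traj$frames[, k, a]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
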