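#' Detect object-investigation frames and bouts
#'
#' A frame counts as investigating when either geometric rule holds:
#' \describe{
#'   \item{approach (rule A)}{2-D nose-to-object-centre distance < 60 mm and
#'     the angle between the neck-to-nose and neck-to-object vectors is
#'     acute (the animal points at the object);}
#'   \item{climb (rule B)}{2-D nose distance < 30 mm and the back is higher
#'     than the object top (no orientation condition).}
#' }
#' Contiguous investigating runs separated by fewer than `merge_gap` frames
#' are merged into one bout; a bout's trigger is `"climb"` if it contains
#' any rule-B frame, otherwise `"approach"`.
#'
#' @param traj a [skeleton_trajectory()].
#' @param obj an [object_spec()].
#' @param approach_dist rule-A distance threshold, mm.
#' @param climb_dist rule-B distance threshold, mm.
#' @param max_angle rule-A orientation half-angle, rad (acute by default).
#' @param merge_gap merge investigating runs separated by fewer than this
#'   many frames.
#' @return List with `mask` (logical per frame) and `bouts` (data.frame
#'   `start`, `end`, `trigger`).
#' @export
detect_investigation <- function(traj, obj, approach_dist = 60,
                                 climb_dist = 30, max_angle = pi / 2,
                                 merge_gap = 5L) {
  stopifnot(inherits(traj, "skeleton_trajectory"),
            inherits(obj, "object_spec"))
  nose <- keypoint(traj, "nose")
  neck <- keypoint(traj, "neck")
  back <- keypoint(traj, "back")
  dx <- nose[, 1] - obj$centre[1]
  dy <- nose[, 2] - obj$centre[2]
  nose_dist <- sqrt(dx^2 + dy^2)
  to_nose <- nose[, 1:2] - neck[, 1:2]
  to_obj <- cbind(obj$centre[1] - neck[, 1], obj$centre[2] - neck[, 2])
  cosang <- rowSums(to_nose * to_obj) /
    (sqrt(rowSums(to_nose^2)) * sqrt(rowSums(to_obj^2)))
  angle <- acos(pmin(1, pmax(-1, cosang)))
  ruleA <- nose_dist < approach_dist & angle < max_angle
  ruleB <- nose_dist < climb_dist & back[, 3] > obj$top_height
  mask <- ruleA | ruleB
  bouts <- .mask_to_bouts(mask, ruleB, merge_gap)
  list(mask = mask, bouts = bouts)
}

.mask_to_bouts <- function(mask, climb_mask, merge_gap) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- c(1L, head(end, -1L) + 1L)
  runs <- data.frame(start = start[r$values], end = end[r$values])
  if (nrow(runs) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      trigger = character(0)))
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L < merge_gap)
      merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  merged$trigger <- vapply(seq_len(nrow(merged)), function(i)
    if (any(climb_mask[merged$start[i]:merged$end[i]])) "climb"
    else "approach", "")
  rownames(merged) <- NULL
  merged
}

#' Classify investigation bouts as deep or shallow
#'
#' A bout is deep when it was climb-triggered, or when any of its frames
#' carries a movement label from `deep_classes` (the classes annotated as
#' sniff/touch/crab interactions in the vocabulary map); otherwise it is
#' shallow.
#'
#' @param bouts data.frame from [detect_investigation()].
#' @param labels a [movement_labels()] covering the bout frames, or NULL to
#'   classify on triggers alone.
#' @param deep_classes integer vector of movement classes counting as deep
#'   interaction.
#' @return `bouts` with an added `depth` column.
#' @export
classify_bouts <- function(bouts, labels = NULL, deep_classes = integer(0)) {
  if (nrow(bouts) == 0L) {
    bouts$depth <- character(0)
    return(bouts)
  }
  has_deep_label <- vapply(seq_len(nrow(bouts)), function(i) {
    if (is.null(labels) || !length(deep_classes)) return(FALSE)
    any(labels$labels[bouts$start[i]:bouts$end[i]] %in% deep_classes)
  }, TRUE)
  bouts$depth <- ifelse(bouts$trigger == "climb" | has_deep_label,
                        "deep", "shallow")
  bouts
}

#' Deep-versus-shallow investigation preference
#'
#' `DSP = asin((T_deep - T_shallow) / (T_deep + T_shallow))`, in radians:
#' `pi/2` is exclusive deep investigation, `-pi/2` exclusive shallow, 0
#' equal preference.
#'
#' @param t_deep,t_shallow total deep/shallow investigation times (s), not
#'   both zero.
#' @return DSP in radians, in `[-pi/2, pi/2]`.
#' @export
dsp <- function(t_deep, t_shallow) {
  if (t_deep < 0 || t_shallow < 0)
    stop("investigation times must be non-negative", call. = FALSE)
  if (t_deep + t_shallow <= 0)
    stop("no investigation: DSP undefined", call. = FALSE)
  asin((t_deep - t_shallow) / (t_deep + t_shallow))
}

#' Full investigation record of a session
#'
#' Runs [detect_investigation()] and [classify_bouts()] against every object
#' in the arena and aggregates deep/shallow times, per-object exploration
#' times and the DSP.
#'
#' @param traj a [skeleton_trajectory()].
#' @param arena an [arena_spec()] with at least one object.
#' @param labels optional [movement_labels()] for label-based depth.
#' @param deep_classes see [classify_bouts()].
#' @param ... thresholds passed to [detect_investigation()].
#' @return An object of class `investigation_record`: list with `bouts`
#'   (incl. object role), `t_deep`, `t_shallow`, `object_times` (named,
#'   seconds) and `dsp` (NA when the session has no investigation).
#' @export
investigation_record <- function(traj, arena, labels = NULL,
                                 deep_classes = integer(0), ...) {
  if (length(arena$objects) == 0L)
    stop("arena has no objects", call. = FALSE)
  fr <- traj$frame_rate
  all_bouts <- list()
  object_times <- c()
  for (obj in arena$objects) {
    det <- detect_investigation(traj, obj, ...)
    b <- classify_bouts(det$bouts, labels, deep_classes)
    if (nrow(b)) b$role <- obj$role
    all_bouts[[length(all_bouts) + 1L]] <- b
    object_times[obj$role] <- sum(det$mask) / fr
  }
  bouts <- do.call(rbind, all_bouts)
  dur <- if (nrow(bouts)) (bouts$end - bouts$start + 1L) / fr else numeric(0)
  t_deep <- sum(dur[bouts$depth == "deep"])
  t_shallow <- sum(dur[bouts$depth == "shallow"])
  structure(list(bouts = bouts, t_deep = t_deep, t_shallow = t_shallow,
                 object_times = object_times,
                 dsp = if (t_deep + t_shallow > 0) dsp(t_deep, t_shallow)
                       else NA_real_),
            class = "investigation_record")
}

#' @export
print.investigation_record <- function(x, ...) {
  cat("Investigation record: ", nrow(x$bouts), " bouts, T_deep = ",
      signif(x$t_deep, 4), " s, T_shallow = ", signif(x$t_shallow, 4),
      " s, DSP = ", signif(x$dsp, 4), " rad\n", sep = "")
  invisible(x)
}
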