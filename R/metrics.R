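#' Movement-fraction vector of a label stream
#'
#' @param stream a [movement_labels()].
#' @return Numeric vector of length `vocabulary_size`, the fraction of
#'   frames spent in each movement class (sums to 1).
#' @export
movement_fractions <- function(stream) {
  stopifnot(inherits(stream, "movement_labels"))
  tabulate(stream$labels, nbins = stream$vocabulary_size) /
    length(stream$labels)
}

#' Select movements whose fractions differ between two groups
#'
#' Per-movement Welch two-sample t test with Sidak family-wise adjustment
#' over the whole vocabulary (`p_adj = 1 - (1 - p)^m`); a movement is
#' selected when its adjusted p-value falls below `alpha`. This reproduces
#' the per-movement post-hoc contrasts of a two-way ANOVA + Sidak analysis
#' for a single-timepoint comparison.
#'
#' @param groupA,groupB matrices of per-animal fraction vectors (animals in
#'   rows), at least 3 animals each.
#' @param alpha family-wise significance level.
#' @return An object of class `movement_comparison`: data.frame with
#'   per-movement means, SEMs, raw and adjusted p-values and a `selected`
#'   flag; the selected indices are in `attr(, "selected")`.
#' @export
select_significant_movements <- function(groupA, groupB, alpha = 0.05) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 3 || nrow(groupB) < 3)
    stop("need at least 3 animals per group", call. = FALSE)
  if (ncol(groupA) != ncol(groupB))
    stop("groups have different vocabulary sizes", call. = FALSE)
  m <- ncol(groupA)
  p_raw <- vapply(seq_len(m), function(k) {
    a <- groupA[, k]; b <- groupB[, k]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
  }, 0)
  p_adj <- 1 - (1 - p_raw)^m
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  out <- data.frame(
    movement = seq_len(m),
    mean_A = colMeans(groupA), sem_A = apply(groupA, 2, sem),
    mean_B = colMeans(groupB), sem_B = apply(groupB, 2, sem),
    p = p_raw, p_adj = p_adj, selected = p_adj < alpha)
  attr(out, "selected") <- which(out$selected)
  class(out) <- c("movement_comparison", "data.frame")
  out
}

#' Time spent in the arena centre
#'
#' Counts frames in which the animal's reference point (the back keypoint)
#' lies within `centre_radius` of the centre of a circular arena. The
#' open-field analysis uses a 50 mm centre zone; the composite-Z input uses
#' 100 mm.
#'
#' @param traj a [skeleton_trajectory()].
#' @param arena a circular [arena_spec()].
#' @param centre_radius zone radius, mm.
#' @return Time in seconds.
#' @export
centre_time <- function(traj, arena, centre_radius = 50) {
  stopifnot(inherits(traj, "skeleton_trajectory"))
  if (arena$shape != "circle")
    stop("centre time is defined for circular arenas", call. = FALSE)
  pos <- keypoint(traj, "back")[, 1:2, drop = FALSE]
  ctr <- arena_centre(arena)
  d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2)
  sum(d < centre_radius) / traj$frame_rate
}

#' Novel-object recognition index
#'
#' `(t_novel - t_familiar) / (t_novel + t_familiar)`, in `[-1, 1]`. The
#' alternative convention, the share of exploration spent on the novel
#' object, is available as [novel_ratio()].
#'
#' @param t_novel,t_familiar exploration times (s), not both zero.
#' @return Dimensionless index.
#' @export
recognition_index <- function(t_novel, t_familiar) {
  if (t_novel < 0 || t_familiar < 0)
    stop("times must be non-negative", call. = FALSE)
  if (t_novel + t_familiar <= 0)
    stop("no exploration time: recognition index undefined", call. = FALSE)
  (t_novel - t_familiar) / (t_novel + t_familiar)
}

#' Share of exploration spent on the novel object
#' @inheritParams recognition_index
#' @return Value in `[0, 1]`.
#' @export
novel_ratio <- function(t_novel, t_familiar) {
  if (t_novel + t_familiar <= 0)
    stop("no exploration time", call. = FALSE)
  t_novel / (t_novel + t_familiar)
}

#' Composite Z score of a battery of three metrics
#'
#' Standardises each of centre time, total exploration time and recognition
#' index against the control group's mean and SD, and sums the three Z
#' scores.
#'
#' @param model named numeric vector (or 1-row data.frame) with
#'   `centre_time`, `total_exploration_time`, `recognition_index`.
#' @param control_mean,control_sd named numeric vectors over the same three
#'   metrics; every SD must be positive.
#' @return The composite Z score (dimensionless).
#' @export
composite_z <- function(model, control_mean, control_sd) {
  metrics <- c("centre_time", "total_exploration_time", "recognition_index")
  model <- unlist(model)[metrics]
  mu <- unlist(control_mean)[metrics]
  sdv <- unlist(control_sd)[metrics]
  if (anyNA(model) || anyNA(mu) || anyNA(sdv))
    stop("model/control inputs must cover: ",
         paste(metrics, collapse = ", "), call. = FALSE)
  if (any(sdv <= 0))
    stop("control SD must be positive for every metric", call. = FALSE)
  sum((model - mu) / sdv)
}
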