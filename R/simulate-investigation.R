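# OU random walk reflected inside an axis-aligned rectangle.
.wander_path <- function(n_frames, speed_scale, lo, hi) {
  rho <- 0.9
  sv <- max(speed_scale, 0.5) / sqrt(2 * log(2))
  xy <- matrix(0, n_frames, 2)
  v <- c(0, 0)
  xy[1, ] <- (lo + hi) / 2
  for (t in 2:n_frames) {
    v <- rho * v + stats::rnorm(2, sd = sv * sqrt(1 - rho^2))
    cand <- xy[t - 1, ] + v
    for (a in 1:2) {
      if (cand[a] < lo[a]) cand[a] <- 2 * lo[a] - cand[a]
      if (cand[a] > hi[a]) cand[a] <- 2 * hi[a] - cand[a]
      cand[a] <- min(max(cand[a], lo[a]), hi[a])
    }
    v <- cand - xy[t - 1, ]
    xy[t, ] <- cand
  }
  xy
}

#' Generate a session realising a scheduled set of investigation bouts
#'
#' Builds a skeleton trajectory in a square novel-object arena in which each
#' scheduled bout is realised geometrically: during a bout the nose sits
#' inside the approach zone (2-D distance to the object centre < 60 mm)
#' pointing at the object; deep bouts additionally contain climbing frames
#' (nose < 30 mm with the back above the object top). Between bouts the
#' animal wanders in the far half of the arena with its nose kept well clear
#' (> 80 mm) of both objects, and whenever it passes near an object it faces
#' away, so the investigation rules cannot fire outside the schedule.
#'
#' @param schedule an [investigation_schedule()].
#' @param arena a square [arena_spec()] with objects covering every role the
#'   schedule uses.
#' @param kin a [kinematic_profile()] controlling wander speed and baseline
#'   height.
#' @param seed RNG seed.
#' @param frame_rate frames per second.
#' @return A [skeleton_trajectory()] of `attr(schedule, "n_frames")` frames.
#' @export
generate_investigation_session <- function(schedule, arena, kin, seed,
                                           frame_rate = 30) {
  stopifnot(inherits(schedule, "investigation_schedule"),
            inherits(arena, "arena_spec"),
            inherits(kin, "kinematic_profile"))
  if (arena$shape != "square")
    stop("investigation sessions use a square object arena", call. = FALSE)
  roles <- vapply(arena$objects, function(o) o$role, "")
  if (!all(schedule$role %in% roles))
    stop("schedule uses roles missing from the arena objects", call. = FALSE)
  n <- attr(schedule, "n_frames")
  set.seed(seed)

  margin <- .body_extent() + 5
  obj_y <- max(vapply(arena$objects, function(o) o$centre[2], 0))
  lo <- c(margin, obj_y + 140)
  hi <- c(arena$size - margin, arena$size - margin)
  if (any(hi - lo < 40))
    stop("arena too small to separate a wander zone from the objects",
         call. = FALSE)
  xy <- .wander_path(n, kin$speed_scale, lo, hi)
  heading <- numeric(n)
  heading[1] <- pi / 2
  for (t in 2:n) {
    d <- xy[t, ] - xy[t - 1, ]
    heading[t] <- if (sqrt(sum(d^2)) > 0.5) atan2(d[2], d[1]) else heading[t - 1]
  }
  hscale <- rep(kin$height_scale, n)

  u <- c(0, 1)                      # approach axis: from object into the arena
  shallow_d <- 45; deep_d <- 20     # nose standoff distances, mm
  nose_fwd <- .body_plan()["nose", "fwd"]
  for (i in seq_len(nrow(schedule))) {
    s <- schedule$start[i]; e <- schedule$end[i]
    obj <- arena$objects[[match(schedule$role[i], roles)]]
    len <- e - s + 1L
    if (schedule$depth[i] == "deep") {
      n_app <- if (len >= 3L) ceiling(0.4 * len) else 0L
      standoff <- c(rep(shallow_d, n_app), rep(deep_d, len - n_app))
      climb <- c(rep(FALSE, n_app), rep(TRUE, len - n_app))
    } else {
      standoff <- rep(shallow_d, len)
      climb <- rep(FALSE, len)
    }
    idx <- s:e
    xy[idx, 1] <- obj$centre[1] + (standoff + nose_fwd) * u[1]
    xy[idx, 2] <- obj$centre[2] + (standoff + nose_fwd) * u[2]
    heading[idx] <- atan2(-u[2], -u[1])   # face the object
    hscale[idx][climb] <- obj$top_height + 15
    # short smooth approach/retreat outside the scheduled frames
    gap_pre <- if (i == 1L) s - 1L else s - 1L - schedule$end[i - 1L]
    L <- min(5L, max(0L, gap_pre - 1L))
    if (L > 0L) {
      a <- s - L
      w <- seq_len(L) / (L + 1)
      xy[a:(s - 1L), ] <- outer(1 - w, xy[a - 1L, ]) + outer(w, xy[s, ])
    }
    gap_post <- if (i == nrow(schedule)) n - e else schedule$start[i + 1L] - e - 1L
    L <- min(5L, max(0L, gap_post - 1L))
    if (L > 0L) {
      b <- e + L
      w <- seq_len(L) / (L + 1)
      xy[(e + 1L):b, ] <- outer(1 - w, xy[e, ]) + outer(w, xy[b + 1L, ])
    }
  }
  # outside scheduled bouts, face away from the nearest object when close
  in_bout <- logical(n)
  for (i in seq_len(nrow(schedule)))
    in_bout[schedule$start[i]:schedule$end[i]] <- TRUE
  for (t in which(!in_bout)) {
    dists <- vapply(arena$objects,
                    function(o) sqrt(sum((xy[t, ] - o$centre)^2)), 0)
    j <- which.min(dists)
    if (dists[j] < 160) {
      away <- xy[t, ] - arena$objects[[j]]$centre
      heading[t] <- atan2(away[2], away[1])
    }
  }
  .assemble_skeleton(xy, heading, hscale, frame_rate = frame_rate)
}
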