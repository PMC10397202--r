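#' The designated discriminative movement classes
#'
#' Fourteen movement modules separate delirium-like from non-delirium
#' animals: eight are elevated (head shaking, walking variants, left turn,
#' freezing, sniffing, gait change) and six reduced (rearing with
#' exploration, launching, hunching, right-looking).
#'
#' @return list with integer vectors `up` and `down`.
#' @export
discriminative_movements <- function() {
  list(up = c(4L, 8L, 9L, 10L, 22L, 34L, 35L, 37L),
       down = c(3L, 16L, 25L, 36L, 38L, 40L))
}

#' Build a group profile for the label generator
#'
#' A profile fixes the expected movement-class fractions of a group and the
#' between-animal spread around them. The POD-like profile shifts the 14
#' discriminative classes away from the control baseline by
#' `effect_size` between-animal standard deviations (up-classes raised,
#' down-classes lowered so fractions still sum to 1).
#'
#' @param label `"control-like"`, `"nonPOD-like"` or `"POD-like"`
#'   (`"nonPOD-like"` is an alias of the control baseline: non-delirium model
#'   animals behave like controls).
#' @param effect_size shift of each elevated discriminative class, in units
#'   of `animal_sd`.
#' @param animal_sd between-animal SD of each class fraction.
#' @param mean_bout_frames expected movement-bout duration (frames).
#' @param vocabulary_size number of movement classes.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(label = c("control-like", "nonPOD-like", "POD-like"),
                          effect_size = 3, animal_sd = 0.004,
                          mean_bout_frames = 9, vocabulary_size = 40) {
  label <- match.arg(label)
  if (mean_bout_frames < 1) stop("mean_bout_frames must be >= 1", call. = FALSE)
  m <- rep(1 / vocabulary_size, vocabulary_size)
  if (label == "POD-like") {
    dm <- discriminative_movements()
    up_shift <- effect_size * animal_sd
    m[dm$up] <- m[dm$up] + up_shift
    # balance so the vector still sums to 1
    m[dm$down] <- m[dm$down] - up_shift * length(dm$up) / length(dm$down)
    if (any(m <= 0))
      stop("effect_size too large for the baseline fractions", call. = FALSE)
  }
  stopifnot(abs(sum(m) - 1) < 1e-9)
  structure(list(fraction_means = m, animal_sd = animal_sd,
                 mean_bout_frames = mean_bout_frames,
                 vocabulary_size = as.integer(vocabulary_size),
                 label = label),
            class = "group_profile")
}

#' Draw per-animal expected fraction vectors from a group profile
#'
#' Each animal's expected fractions are the group means plus independent
#' Gaussian between-animal noise (SD `profile$animal_sd`), floored at a small
#' positive value and renormalised.
#'
#' @param profile a [group_profile()].
#' @param n_animals number of animals.
#' @param seed RNG seed.
#' @return `n_animals x vocabulary_size` matrix, rows summing to 1.
#' @export
animal_fractions <- function(profile, n_animals, seed) {
  stopifnot(inherits(profile, "group_profile"), n_animals >= 1)
  set.seed(seed)
  p <- profile$vocabulary_size
  X <- matrix(stats::rnorm(n_animals * p, mean = rep(profile$fraction_means,
                                                     each = n_animals),
                           sd = profile$animal_sd),
              nrow = n_animals)
  X[X < 1e-6] <- 1e-6
  X / rowSums(X)
}

#' Build a kinematic profile for the skeleton generator
#'
#' @param label `"Hyper"` or `"Hypo"`. Defaults encode the two psychomotor
#'   subtypes: the hyperactive preset moves at twice the speed scale of the
#'   hypoactive one and carries itself higher.
#' @param speed_scale median per-frame body displacement, mm/frame.
#' @param height_scale nominal back height, mm.
#' @param turn_rate heading diffusion, rad/frame.
#' @return An object of class `kinematic_profile`.
#' @export
kinematic_profile <- function(label = c("Hyper", "Hypo"), speed_scale = NULL,
                              height_scale = NULL, turn_rate = 0.15) {
  label <- match.arg(label)
  if (is.null(speed_scale)) speed_scale <- if (label == "Hyper") 4 else 2
  if (is.null(height_scale)) height_scale <- if (label == "Hyper") 28 else 22
  if (speed_scale < 0) stop("speed_scale must be >= 0", call. = FALSE)
  if (height_scale <= 0 || turn_rate <= 0)
    stop("scales must be > 0", call. = FALSE)
  structure(list(speed_scale = speed_scale, height_scale = height_scale,
                 turn_rate = turn_rate, label = label),
            class = "kinematic_profile")
}

#' Build an investigation schedule
#'
#' Ground-truth bout plan consumed by [generate_investigation_session()].
#'
#' @param start,end integer vectors of 1-based inclusive bout frames.
#' @param role character vector, `"familiar"`/`"novel"` per bout.
#' @param depth character vector, `"deep"`/`"shallow"` per bout.
#' @param n_frames session length the schedule must fit into.
#' @param min_gap minimum gap (frames) enforced between consecutive bouts;
#'   must exceed the detector's bout-merge gap for exact recovery.
#' @return data.frame of class `investigation_schedule`.
#' @export
investigation_schedule <- function(start, end, role, depth, n_frames,
                                   min_gap = 10L) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   role = role, depth = depth, stringsAsFactors = FALSE)
  df <- df[order(df$start), , drop = FALSE]
  if (any(df$end < df$start)) stop("bout with end < start", call. = FALSE)
  if (any(df$start < 1L) || any(df$end > n_frames))
    stop("bouts must lie within 1..n_frames", call. = FALSE)
  if (nrow(df) > 1L && any(df$start[-1L] - df$end[-nrow(df)] <= min_gap))
    stop("bouts must be separated by more than ", min_gap, " frames",
         call. = FALSE)
  if (!all(df$role %in% c("familiar", "novel")))
    stop("role must be familiar/novel", call. = FALSE)
  if (!all(df$depth %in% c("deep", "shallow")))
    stop("depth must be deep/shallow", call. = FALSE)
  attr(df, "n_frames") <- as.integer(n_frames)
  class(df) <- c("investigation_schedule", "data.frame")
  df
}
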