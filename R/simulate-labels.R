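#' Generate a bout-structured movement-label stream
#'
#' Labels are produced by a semi-Markov scheme: bout classes are drawn
#' independently with probabilities proportional to the profile's expected
#' fractions, bout durations are geometric with mean
#' `profile$mean_bout_frames`, and the stream is truncated to `n_frames`.
#' Empirical class fractions converge to `fraction_means` as the stream
#' grows.
#'
#' @param profile a [group_profile()], or a bare probability vector summing
#'   to 1 (taken as the expected fractions of one animal).
#' @param n_frames number of frames to generate.
#' @param seed RNG seed.
#' @return A [movement_labels()].
#' @export
generate_labels <- function(profile, n_frames, seed) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (inherits(profile, "group_profile")) {
    p <- profile$fraction_means
    mb <- profile$mean_bout_frames
    vs <- profile$vocabulary_size
  } else {
    p <- as.numeric(profile)
    if (abs(sum(p) - 1) > 1e-6 || any(p < 0))
      stop("fraction vector must be non-negative and sum to 1", call. = FALSE)
    mb <- 9
    vs <- length(p)
  }
  set.seed(seed)
  out <- integer(0)
  # draw bouts in blocks until the stream is long enough
  while (length(out) < n_frames) {
    n_b <- max(16L, ceiling(1.3 * (n_frames - length(out)) / mb))
    cls <- sample.int(vs, n_b, replace = TRUE, prob = p)
    dur <- 1L + stats::rgeom(n_b, prob = 1 / mb)
    out <- c(out, rep(cls, dur))
  }
  movement_labels(out[seq_len(n_frames)], vocabulary_size = vs)
}
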