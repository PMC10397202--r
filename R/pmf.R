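#' Probability mass function of a pose feature
#'
#' Histograms the series into `bins` equal-width bins spanning the observed
#' range and normalises counts to probabilities. A constant series gets a
#' symmetrically widened range so that the single occupied bin is
#' well-defined.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param bins number of bins (default 50).
#' @return An object of class `pmf_curve` with `bin_edges` (length
#'   `bins + 1`) and `probabilities` (length `bins`, summing to 1).
#' @export
pmf <- function(values, bins = 50) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need >= 2 finite values", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  structure(list(bin_edges = edges, probabilities = counts / sum(counts)),
            class = "pmf_curve")
}

#' @export
print.pmf_curve <- function(x, ...) {
  cat("PMF curve: ", length(x$probabilities), " bins over [",
      signif(x$bin_edges[1], 4), ", ",
      signif(x$bin_edges[length(x$bin_edges)], 4), "]\n", sep = "")
  invisible(x)
}

#' Plot a PMF curve
#' @param x a [pmf()] curve.
#' @param ... passed to [plot()].
#' @export
plot.pmf_curve <- function(x, ...) {
  mid <- (head(x$bin_edges, -1) + x$bin_edges[-1]) / 2
  plot(mid, x$probabilities, type = "l", xlab = "value",
       ylab = "probability", ...)
  invisible(x)
}

#' Seven descriptor statistics of a PMF curve
#'
#' Treats the 50 bin probabilities as a discrete signal and computes, in
#' fixed order: mean, median, standard deviation, 25% quantile, 75% quantile,
#' minimum and maximum. With `on = "values"` the same seven statistics are
#' instead computed on the underlying feature distribution implied by the
#' curve (bin midpoints weighted by probability), the more common
#' distribution-level alternative.
#'
#' @param curve a [pmf()] curve.
#' @param on `"probabilities"` (default) or `"values"`.
#' @return Named numeric vector of length 7.
#' @export
summarize_pmf <- function(curve, on = c("probabilities", "values")) {
  on <- match.arg(on)
  if (on == "probabilities") {
    p <- curve$probabilities
    q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
    c(mean = mean(p), median = q[2], sd = stats::sd(p),
      q25 = q[1], q75 = q[3], min = min(p), max = max(p))
  } else {
    mid <- (head(curve$bin_edges, -1) + curve$bin_edges[-1]) / 2
    p <- curve$probabilities
    mu <- sum(mid * p)
    cdf <- cumsum(p)
    qq <- vapply(c(0.25, 0.5, 0.75),
                 function(a) mid[which(cdf >= a)[1]], 0)
    occ <- mid[p > 0]
    c(mean = mu, median = qq[2],
      sd = sqrt(sum(p * (mid - mu)^2)),
      q25 = qq[1], q75 = qq[3], min = min(occ), max = max(occ))
  }
}

#' Pose-feature summary (eigenvalue) vector of a trajectory
#'
#' Pipeline: per-frame features -> 50-bin PMF per feature -> 7 descriptor
#' statistics per curve, concatenated in `feature_list` order. The default
#' 13-feature configuration yields 91 values; the reduced 11-feature
#' configuration yields 77.
#'
#' @param traj a [skeleton_trajectory()].
#' @param feature_list feature names ([pose_feature_set()]).
#' @param bins PMF bins.
#' @param on see [summarize_pmf()].
#' @return Named numeric vector of length `7 * length(feature_list)`.
#' @export
eigenvalue_vector <- function(traj, feature_list = pose_feature_set(),
                              bins = 50, on = "probabilities") {
  feats <- compute_pose_features(traj, feature_list)
  blocks <- lapply(feature_list, function(f) {
    s <- summarize_pmf(pmf(feats[[f]], bins = bins), on = on)
    names(s) <- paste(f, names(s), sep = ".")
    s
  })
  unlist(blocks)
}
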