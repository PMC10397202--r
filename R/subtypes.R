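#' Cluster delirium-like animals into Hyper/Hypo subtypes
#'
#' Columns of the pose-summary (eigenvalue) matrix are standardised
#' (zero-variance columns dropped), reduced to 3-D with the same embedding
#' machinery as the behaviour space, and split by seeded k-means. The
#' cluster with the larger mean of the speed-feature block means (back,
#' nose and front-claw speeds) is named Hyper, the other Hypo, so the
#' naming never depends on arbitrary cluster indices.
#'
#' @param E animals x summary-statistics matrix from [eigenvalue_vector()]
#'   rows (column names of the form `feature.stat`). For subtype separation
#'   build it with `on = "values"`: the probability-level descriptors are
#'   nearly invariant to the location and scale of a feature's distribution
#'   (each animal's PMF spans its own range), which is precisely the
#'   kinematic signal that distinguishes hyperactive from hypoactive
#'   animals.
#' @param seed RNG seed for k-means.
#' @param k number of clusters (default 2).
#' @param neighbor_param embedding neighbourhood parameter.
#' @return An object of class `subtype_result`: list with `subtype` (per
#'   animal), `cluster` (k-means indices), `Y` (3-D coordinates), `centers`.
#' @export
cluster_subtypes <- function(E, seed = 1, k = 2, neighbor_param = 6) {
  E <- as.matrix(E)
  if (nrow(E) < 2 * k)
    stop("need at least ", 2 * k, " animals for k = ", k, call. = FALSE)
  sds <- apply(E, 2, stats::sd)
  Z <- scale(E[, sds > 0, drop = FALSE])
  Y <- embed_fractions(Z, seed = seed, neighbor_param = neighbor_param)
  set.seed(seed)
  km <- stats::kmeans(Y, centers = k, nstart = 20)
  speed_cols <- grep("^(back|nose|left_front_claw|right_front_claw)_speed\\.mean$",
                     colnames(E))
  subtype <- rep(NA_character_, nrow(E))
  if (length(speed_cols) && k == 2) {
    sp <- rowMeans(E[, speed_cols, drop = FALSE])
    m1 <- mean(sp[km$cluster == 1]); m2 <- mean(sp[km$cluster == 2])
    hyper <- if (m1 >= m2) 1L else 2L
    subtype <- ifelse(km$cluster == hyper, "Hyper", "Hypo")
  }
  structure(list(subtype = unname(subtype), cluster = unname(km$cluster),
                 Y = Y,
                 centers = km$centers, seed = seed),
            class = "subtype_result")
}

#' @export
print.subtype_result <- function(x, ...) {
  if (all(is.na(x$subtype)))
    cat("Subtype clustering: ", length(unique(x$cluster)), " clusters over ",
        length(x$cluster), " animals\n", sep = "")
  else
    cat("Subtype clustering: ", sum(x$subtype == "Hyper"), " Hyper / ",
        sum(x$subtype == "Hypo"), " Hypo\n", sep = "")
  invisible(x)
}

#' Compare pose-feature distributions between two groups of animals
#'
#' Each group's per-frame feature values are pooled across animals,
#' histogrammed into a PMF, and the two curves compared with the
#' EDF-resampling KS test, one result per feature.
#'
#' @param groupA,groupB lists of [skeleton_trajectory()] objects.
#' @param feature_list feature names ([pose_feature_set()]).
#' @param bins PMF bins.
#' @param n_resample,alpha,seed see [ks_resample_test()].
#' @return Named list of `ks_result`, one per feature.
#' @export
compare_subtype_features <- function(groupA, groupB,
                                     feature_list = pose_feature_set(),
                                     bins = 50, n_resample = 500,
                                     alpha = 0.05, seed = 1) {
  if (!length(groupA) || !length(groupB))
    stop("both groups need at least one animal", call. = FALSE)
  pool <- function(group, f)
    unlist(lapply(group, function(tr) compute_pose_features(tr, f)[[f]]))
  out <- list()
  for (i in seq_along(feature_list)) {
    f <- feature_list[i]
    out[[f]] <- ks_resample_test(pmf(pool(groupA, f), bins),
                                 pmf(pool(groupB, f), bins),
                                 n_resample = n_resample, alpha = alpha,
                                 seed = seed + i)
  }
  out
}
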