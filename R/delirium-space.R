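#' Diagnose delirium-like animals by unsupervised clustering
#'
#' Fraction vectors of model and control animals are z-scored per movement
#' across all samples and cut into two clusters (Ward agglomerative
#' clustering on Euclidean distances). The cluster holding the larger share
#' of control animals is the non-delirium side; model animals in the other
#' cluster are labelled POD -- but only when cluster membership is actually
#' associated with group (Fisher exact test at `gate_alpha`), so that
#' homogeneous model groups indistinguishable from controls come out all
#' nonPOD rather than arbitrarily split.
#'
#' @param model,control matrices of per-animal fraction vectors (animals in
#'   rows).
#' @param seed RNG seed (recorded; the procedure itself is deterministic).
#' @param gate_alpha significance level of the cluster-group association
#'   gate.
#' @return An object of class `pod_diagnosis`: list with `labels` (per model
#'   animal, `"POD"`/`"nonPOD"`), `cluster` (per sample over
#'   model-then-control rows), `gate_p`, `hclust` (linkage metadata), `seed`.
#' @export
diagnose_pod <- function(model, control, seed = 1, gate_alpha = 0.05) {
  model <- as.matrix(model); control <- as.matrix(control)
  if (nrow(model) < 1 || nrow(control) < 1)
    stop("both groups must be non-empty", call. = FALSE)
  X <- rbind(model, control)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0))
    stop("all samples identical: clustering is degenerate", call. = FALSE)
  Z <- scale(X[, sds > 0, drop = FALSE])
  hc <- stats::hclust(stats::dist(Z), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  is_model <- rep(c(TRUE, FALSE), c(nrow(model), nrow(control)))
  ctrl_in_1 <- sum(cl == 1L & !is_model)
  ctrl_in_2 <- sum(cl == 2L & !is_model)
  nonpod_cluster <- if (ctrl_in_1 >= ctrl_in_2) 1L else 2L
  gate_p <- stats::fisher.test(table(factor(cl, levels = 1:2),
                                     factor(is_model,
                                            levels = c(FALSE, TRUE))))$p.value
  labels <- rep("nonPOD", nrow(model))
  if (gate_p < gate_alpha)
    labels[cl[seq_len(nrow(model))] != nonpod_cluster] <- "POD"
  structure(list(labels = labels, cluster = cl, gate_p = gate_p,
                 nonpod_cluster = nonpod_cluster, hclust = hc, seed = seed),
            class = "pod_diagnosis")
}

#' @export
print.pod_diagnosis <- function(x, ...) {
  cat("POD diagnosis: ", sum(x$labels == "POD"), " POD / ",
      sum(x$labels == "nonPOD"), " nonPOD model animals (association p = ",
      signif(x$gate_p, 3), ")\n", sep = "")
  invisible(x)
}

#' Embed fraction vectors into the 3-D behaviour space
#'
#' Exact t-SNE to three dimensions with the neighbourhood (perplexity)
#' parameter set to 6 by default. The embedding is a deterministic function
#' of the data (PCA initialisation), so identical inputs always give
#' identical coordinates.
#'
#' @param X samples x features fraction matrix (>= 4 samples).
#' @param seed RNG seed (recorded for provenance).
#' @param neighbor_param perplexity-like neighbourhood size.
#' @return `nrow(X) x 3` coordinate matrix.
#' @export
embed_fractions <- function(X, seed = 1, neighbor_param = 6) {
  X <- as.matrix(X)
  Y <- .tsne_exact(X, dims = 3, perplexity = neighbor_param)
  attr(Y, "seed") <- seed
  Y
}

#' Fit a linear decision boundary in the embedded space
#'
#' Max-margin linear separator (support-vector machine, linear kernel, unit
#' cost) between the two label groups in 3-D.
#'
#' @param Y embedded coordinates (samples x 3).
#' @param labels two-level factor or character vector.
#' @return List with `w` (3-vector normal), `b` (offset), `positive` (the
#'   label on the positive side), and the fitted `svm` object.
#' @export
fit_boundary <- function(Y, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    stop("need exactly two label groups", call. = FALSE)
  Y <- as.matrix(Y)
  fit <- e1071::svm(Y, labels, kernel = "linear", scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients the score so the first factor level is positive
  list(w = w, b = b, positive = levels(labels)[1], svm = fit)
}

#' Signed projection of embedded points onto the boundary normal
#'
#' `s_i = (w . y_i + b) / ||w||`: the signed Euclidean distance of each
#' point from the decision plane, oriented so the POD side is positive when
#' `pod_label` is supplied. `raw = TRUE` returns the unnormalised decision
#' values `w . y + b` instead.
#'
#' @param Y embedded coordinates.
#' @param boundary a [fit_boundary()] result.
#' @param pod_label label that should project positive (default the
#'   boundary's own positive class).
#' @param raw return unnormalised decision values.
#' @return Numeric vector of projection values.
#' @export
project_onto_boundary <- function(Y, boundary, pod_label = NULL, raw = FALSE) {
  w <- boundary$w; b <- boundary$b
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("degenerate boundary: ||w|| = 0", call. = FALSE)
  s <- drop(as.matrix(Y) %*% w + b)
  if (!is.null(pod_label) && !identical(pod_label, boundary$positive))
    s <- -s
  if (raw) s else s / nw
}

#' Fit the delirium-like behaviour space
#'
#' End-to-end fit over model and control fraction vectors: discriminative
#' movements are selected ([select_significant_movements()]), model animals
#' are diagnosed POD/nonPOD ([diagnose_pod()]), the POD and nonPOD animals'
#' selected-movement fractions are embedded in 3-D ([embed_fractions()]), a
#' linear boundary is fitted between them and every animal receives a signed
#' projection value.
#'
#' @param model,control matrices of per-animal 40-movement fraction vectors.
#' @param seed RNG seed propagated to all stages.
#' @param neighbor_param embedding neighbourhood parameter.
#' @param alpha selection significance level.
#' @param movements optional integer vector forcing the movement set
#'   (bypasses selection).
#' @return An object of class `pod_space` with the diagnosis, selected
#'   movements, embedding `Y`, `boundary`, and per-animal `projection`
#'   (POD-positive signed distances).
#' @export
pod_space <- function(model, control, seed = 1, neighbor_param = 6,
                      alpha = 0.05, movements = NULL) {
  model <- as.matrix(model); control <- as.matrix(control)
  diag_res <- diagnose_pod(model, control, seed = seed)
  if (is.null(movements)) {
    pod_rows <- model[diag_res$labels == "POD", , drop = FALSE]
    non_rows <- model[diag_res$labels == "nonPOD", , drop = FALSE]
    comp <- if (nrow(pod_rows) >= 3 && nrow(non_rows) >= 3)
      select_significant_movements(pod_rows, non_rows, alpha = alpha)
    else NULL
    movements <- if (!is.null(comp) && length(attr(comp, "selected")))
      attr(comp, "selected")
    else sort(unlist(discriminative_movements()))
  } else comp <- NULL
  lab <- diag_res$labels
  if (!all(c("POD", "nonPOD") %in% lab))
    stop("pod_space needs both POD and nonPOD animals in the model group",
         call. = FALSE)
  Xsel <- model[, movements, drop = FALSE]
  Y <- embed_fractions(Xsel, seed = seed, neighbor_param = neighbor_param)
  boundary <- fit_boundary(Y, lab)
  projection <- project_onto_boundary(Y, boundary, pod_label = "POD")
  flip <- mean(projection[lab == "POD"]) < 0
  if (flip) projection <- -projection
  structure(list(diagnosis = diag_res, movements = movements,
                 comparison = comp, X = Xsel, Y = Y, boundary = boundary,
                 projection = projection, labels = lab, flip = flip,
                 seed = seed, neighbor_param = neighbor_param),
            class = "pod_space")
}

#' @export
print.pod_space <- function(x, ...) {
  cat("Delirium-like behaviour space\n",
      "  movements: ", length(x$movements), " (",
      paste0("M", x$movements, collapse = ", "), ")\n",
      "  animals:   ", sum(x$labels == "POD"), " POD, ",
      sum(x$labels == "nonPOD"), " nonPOD\n",
      "  projection: POD ", signif(mean(x$projection[x$labels == "POD"]), 4),
      " / nonPOD ",
      signif(mean(x$projection[x$labels == "nonPOD"]), 4), " (mean)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.pod_space <- function(object, ...) {
  s <- split(object$projection, object$labels)
  out <- data.frame(
    group = names(s),
    n = vapply(s, length, 0L),
    projection_mean = vapply(s, mean, 0),
    projection_sd = vapply(s, stats::sd, 0))
  rownames(out) <- NULL
  out
}

#' @export
coef.pod_space <- function(object, ...) {
  c(w = object$boundary$w, b = object$boundary$b)
}

#' Project new fraction vectors into a fitted behaviour space
#'
#' t-SNE has no parametric out-of-sample map, so new animals are placed at
#' the affinity-weighted average of their `k` nearest training animals'
#' embedded coordinates, then projected onto the fitted boundary.
#'
#' @param object a [pod_space()] fit.
#' @param newdata matrix of 40-movement fraction vectors (or already reduced
#'   to the fit's movement columns).
#' @param k number of nearest neighbours for placement.
#' @param ... unused.
#' @return data.frame with embedded coordinates, `projection` and predicted
#'   `label`.
#' @export
predict.pod_space <- function(object, newdata, k = 3, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$X)) {
    if (ncol(newdata) >= max(object$movements))
      newdata <- newdata[, object$movements, drop = FALSE]
    else stop("newdata has ", ncol(newdata), " columns; expected ",
              ncol(object$X), " or a full fraction matrix", call. = FALSE)
  }
  Ynew <- matrix(0, nrow(newdata), 3)
  for (i in seq_len(nrow(newdata))) {
    d <- sqrt(colSums((t(object$X) - newdata[i, ])^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    wts <- 1 / pmax(d[nn], 1e-12)
    Ynew[i, ] <- colSums(object$Y[nn, , drop = FALSE] * wts) / sum(wts)
  }
  proj <- project_onto_boundary(Ynew, object$boundary, pod_label = "POD")
  if (isTRUE(object$flip)) proj <- -proj
  data.frame(y1 = Ynew[, 1], y2 = Ynew[, 2], y3 = Ynew[, 3],
             projection = proj,
             label = ifelse(proj > 0, "POD", "nonPOD"))
}

#' Plot a fitted behaviour space
#'
#' Two panels: the first two embedding coordinates coloured by diagnosis,
#' and the 1-D projection values.
#'
#' @param x a [pod_space()] fit.
#' @param ... unused.
#' @export
plot.pod_space <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  col <- ifelse(x$labels == "POD", "#d6604d", "#4393c3")
  plot(x$Y[, 1], x$Y[, 2], col = col, pch = 19,
       xlab = "dim 1", ylab = "dim 2", main = "behaviour space")
  graphics::legend("topright", c("POD", "nonPOD"),
                   col = c("#d6604d", "#4393c3"), pch = 19, bty = "n")
  graphics::stripchart(split(x$projection, x$labels), vertical = TRUE,
                       pch = 19, col = c("#4393c3", "#d6604d"),
                       method = "jitter", ylab = "projection value",
                       main = "boundary projection")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
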