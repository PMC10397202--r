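#' Train the POD/nonPOD logistic classifier
#'
#' Ridge-penalised logistic regression on selected-movement fractions. The
#' regularisation strength is chosen from `iterations` log-spaced candidate
#' values by minimising stratified `folds`-fold cross-validated
#' classification error; the best-so-far error over the candidate sequence
#' forms the (non-increasing) minimum-classification-error curve, and a
#' pooled confusion matrix across folds is kept for the chosen
#' configuration.
#'
#' @param X samples x features fraction matrix.
#' @param labels two-level factor/character vector (`"POD"`/`"nonPOD"` or
#'   similar).
#' @param folds CV folds (default 5).
#' @param iterations number of candidate regularisation strengths (default
#'   30).
#' @param seed RNG seed controlling fold assignment.
#' @return An object of class `pod_classifier`: `fit` (glmnet), `lambda`,
#'   `cv_error` (per candidate), `error_curve` (best-so-far),
#'   `confusion` (2x2, chosen configuration), `levels`, `positive`.
#' @export
train_classifier <- function(X, labels, folds = 5, iterations = 30,
                             seed = 1) {
  X <- as.matrix(X)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) != 2)
    stop("need exactly two classes to train", call. = FALSE)
  if (nrow(X) < folds) stop("fewer samples than folds", call. = FALSE)
  set.seed(seed)
  # stratified fold assignment
  foldid <- integer(nrow(X))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  lambdas <- 10^seq(1, -5, length.out = iterations)
  err <- matrix(NA_real_, folds, iterations)
  conf <- array(0, c(2, 2, iterations))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    if (nlevels(droplevels(labels[tr])) < 2) next
    # glmnet warns when a fold holds < 8 members of a class; expected at
    # the cohort sizes this runs at
    fit <- suppressWarnings(
      glmnet::glmnet(X[tr, , drop = FALSE], labels[tr],
                     family = "binomial", alpha = 0, lambda = lambdas))
    pr <- predict(fit, X[!tr, , drop = FALSE], s = lambdas, type = "class")
    truth <- labels[!tr]
    for (j in seq_len(iterations)) {
      pred <- factor(pr[, j], levels = levels(labels))
      err[f, j] <- mean(pred != truth)
      conf[, , j] <- conf[, , j] + table(truth, pred)
    }
  }
  cv_error <- colMeans(err, na.rm = TRUE)
  best <- which.min(cv_error)
  fit <- suppressWarnings(
    glmnet::glmnet(X, labels, family = "binomial", alpha = 0,
                   lambda = lambdas))
  structure(list(fit = fit, lambdas = lambdas, lambda = lambdas[best],
                 cv_error = cv_error, error_curve = cummin(cv_error),
                 confusion = conf[, , best], levels = levels(labels),
                 positive = levels(labels)[2], foldid = foldid,
                 seed = seed),
            class = "pod_classifier")
}

#' @export
print.pod_classifier <- function(x, ...) {
  cat("POD classifier (ridge logistic): lambda = ", signif(x$lambda, 3),
      ", CV error = ", signif(min(x$cv_error), 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pod_classifier <- function(object, ...) {
  drop(as.matrix(stats::coef(object$fit, s = object$lambda)))
}

#' Predict labels for new animals
#'
#' @param object a [train_classifier()] fit.
#' @param newdata fraction matrix with the training feature columns.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.pod_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$fit$dim[1])
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$fit$dim[1], call. = FALSE)
  if (nrow(newdata) == 0) stop("empty newdata", call. = FALSE)
  as.character(predict(object$fit, newdata, s = object$lambda,
                       type = "class"))
}

#' Label a treated group and compute POD incidence
#'
#' @param model a [train_classifier()] fit.
#' @param X_new fraction matrix of the treated animals.
#' @param pod_label which class counts as POD (default `"POD"` when present
#'   among the training levels, else the second level).
#' @return An object of class `incidence_result`: `labels`, `n_total`,
#'   `n_pod`, `incidence` (percent).
#' @export
predict_and_incidence <- function(model, X_new, pod_label = NULL) {
  labels <- predict(model, X_new)
  if (is.null(pod_label))
    pod_label <- if ("POD" %in% model$levels) "POD" else model$levels[2]
  n_pod <- sum(labels == pod_label)
  structure(list(labels = labels, n_total = length(labels), n_pod = n_pod,
                 incidence = 100 * n_pod / length(labels),
                 pod_label = pod_label),
            class = "incidence_result")
}

#' @export
print.incidence_result <- function(x, ...) {
  cat("Incidence: ", x$n_pod, "/", x$n_total, " = ",
      round(x$incidence, 1), "% labelled ", x$pod_label, "\n", sep = "")
  invisible(x)
}
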