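# Exact t-SNE for the small sample sizes this package works at (tens of
# animals): full pairwise affinities, per-point precision calibrated to the
# target perplexity by binary search, KL gradient descent with momentum and
# early exaggeration. Initialisation is the first three principal
# components (scaled to SD 1e-4), which makes the embedding a deterministic,
# permutation-equivariant function of the data.
.tsne_exact <- function(X, dims = 3, perplexity = 6, max_iter = 600,
                        eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples to embed", call. = FALSE)
  if (n - 1 <= perplexity)
    stop("neighbor_param (perplexity) too large for ", n, " samples",
         call. = FALSE)
  # optimise over a canonical (lexicographic) row order so the result is an
  # exactly permutation-equivariant function of the data, then restore the
  # caller's order
  ord <- do.call(order, as.data.frame(X))
  Y <- .tsne_core(X[ord, , drop = FALSE], dims, perplexity, max_iter, eta)
  out <- Y
  out[ord, ] <- Y
  out
}

.tsne_core <- function(X, dims, perplexity, max_iter, eta) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2

  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in 1:n) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { H <- 0 }
      else H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                          else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  # PCA init, padded with zero columns if the data have rank < dims.
  # Component signs are anchored on the feature-space loadings (which do not
  # depend on sample order), keeping the whole embedding
  # permutation-equivariant.
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = min(dims, n), nv = min(dims, ncol(X)))
  k <- sum(sv$d > 1e-12)
  Y <- matrix(0, n, dims)
  if (k > 0) {
    m <- min(k, dims)
    flip <- vapply(seq_len(m), function(j) {
      v <- sv$v[, j]
      if (v[which.max(abs(v))] < 0) -1 else 1
    }, 0)
    pcs <- sv$u[, seq_len(m), drop = FALSE] *
      rep(flip * sv$d[seq_len(m)], each = n)
    Y[, seq_len(m)] <- pcs / stats::sd(pcs[, 1]) * 1e-4
  }

  inc <- matrix(0, n, dims)
  for (it in seq_len(max_iter)) {
    ex <- if (it <= 100) 4 else 1
    mom <- if (it <= 250) 0.5 else 0.8
    W <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(W) <- 0
    Q <- pmax(W / sum(W), 1e-12)
    L <- (ex * P - Q) * W
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    inc <- mom * inc - eta * G
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  .canonical_orientation(Y)
}

# The KL objective is invariant to rotations/reflections of the embedding,
# so the raw optimiser output carries an arbitrary orientation. Rotate to
# the embedding's own principal axes and anchor each axis sign on the third
# moment (falling back to the largest-|coordinate| point), making the
# returned coordinates independent of sample order and of orientation drift.
.canonical_orientation <- function(Y) {
  Yc <- sweep(Y, 2, colMeans(Y))
  e <- eigen(crossprod(Yc), symmetric = TRUE)
  R <- e$vectors
  Yr <- Yc %*% R
  for (j in seq_len(ncol(Yr))) {
    m3 <- sum(Yr[, j]^3)
    s <- if (abs(m3) > 1e-8) sign(m3)
         else sign(Yr[which.max(abs(Yr[, j])), j])
    if (s < 0) Yr[, j] <- -Yr[, j]
  }
  Yr
}
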