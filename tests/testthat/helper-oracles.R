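# Independent brute-force reference implementations used as oracles.
# Deliberately naive: explicit loops and normal-equations fits, sharing no
# code with the package's optimized paths.

# OLS line fit of v against k by the normal equations, residuals returned
naive_ols_residuals <- function(k, v) {
  A <- cbind(1, k)
  beta <- solve(t(A) %*% A, t(A) %*% v)
  v - as.vector(A %*% beta)
}

naive_window_cov <- function(M, N, S, i) {
  k <- i:(i + S)
  rm <- naive_ols_residuals(k, M[k])
  rn <- naive_ols_residuals(k, N[k])
  sum(rm * rn) / (S + 1)
}

naive_segment_cov <- function(M, N, S) {
  L <- length(M)
  tot <- 0
  for (i in seq_len(L - S)) tot <- tot + naive_window_cov(M, N, S, i)
  tot / (L - S)
}

naive_dcca_coefficient <- function(colA, colB, S) {
  M <- cumsum(colA); N <- cumsum(colB)
  naive_segment_cov(M, N, S) /
    (sqrt(naive_segment_cov(M, M, S)) * sqrt(naive_segment_cov(N, N, S)))
}

naive_dcca_features <- function(mat, S) {
  out <- numeric(0)
  for (a in 1:19) for (b in (a + 1):20)
    out <- c(out, naive_dcca_coefficient(mat[, a], mat[, b], S))
  out
}

# local scatter matrices by the O(n^2) double loop over the printed weights
naive_scatter <- function(X, y, A) {
  n <- nrow(X); d <- ncol(X)
  counts <- table(y)
  Sw <- matrix(0, d, d); Sb <- matrix(0, d, d)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- X[i, ] - X[j, ]
    op <- outer(dx, dx)
    if (y[i] == y[j]) {
      nl <- counts[[as.character(y[i])]]
      Sw <- Sw + (A[i, j] / nl) * op / 2
      Sb <- Sb + A[i, j] * (1 / n - 1 / nl) * op / 2
    } else {
      Sb <- Sb + (1 / n) * op / 2
    }
  }
  list(Sw = Sw, Sb = Sb)
}

# classical (non-local) within-class scatter sum_l sum_{i in l} (x - mu_l)^2
classical_within_scatter <- function(X, y) {
  d <- ncol(X)
  S <- matrix(0, d, d)
  for (cl in unique(y)) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    for (i in seq_len(nrow(Xc))) {
      dx <- Xc[i, ] - mu
      S <- S + outer(dx, dx)
    }
  }
  S
}

# random normalized-PSSM-shaped matrix with entries in (0, 1)
rand_npssm <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(L * 20), L, 20)
}

# tiny raw PSSM with integer scores in the typical range
rand_raw_pssm <- function(id, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw_pssm(id, matrix(sample(-9:11, L * 20, replace = TRUE), L, 20))
}
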