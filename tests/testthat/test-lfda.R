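test_that("local scaling equals the K-th neighbor distance", {
  # 9 points on a line at 0..8: the point at 0 has 7th neighbor at distance 7
  X <- cbind(0:8, 0)
  sig <- local_scaling(X, K = 7)
  expect_equal(sig[1], 7)
  expect_equal(sig[9], 7)
  expect_equal(sig[5], 4)  # middle point: neighbors at 1,1,2,2,3,3,4

  set.seed(31)
  Xr <- matrix(rnorm(150), 30, 5)
  D <- as.matrix(dist(Xr))
  sig <- local_scaling(Xr, K = 7)
  for (i in 1:30)
    expect_equal(sig[i], unname(sort(D[i, -i])[7]), tolerance = 1e-12)

  expect_error(local_scaling(Xr[1:5, ], K = 7), "lower K")
  expect_warning(s0 <- local_scaling(matrix(1, 9, 2), K = 7), "zero local")
  expect_equal(s0, rep(1e-12, 9))
})

test_that("affinity matrix is symmetric with unit diagonal and unit exponent", {
  set.seed(32)
  X <- matrix(rnorm(40), 20, 2)
  sig <- local_scaling(X, 7)
  A <- affinity_matrix(X, sig)
  expect_equal(diag(A), rep(1, 20))
  expect_lt(max(abs(A - t(A))), 1e-12)
  expect_true(all(A > 0 & A <= 1))

  # two points at distance sigma1*sigma2 -> affinity exp(-1)
  X2 <- rbind(0, 2)
  A2 <- affinity_matrix(X2, sigma = c(2, 1))
  expect_equal(A2[1, 2], exp(-1))

  # squared variant
  A2s <- affinity_matrix(X2, sigma = c(2, 1), variant = "squared")
  expect_equal(A2s[1, 2], exp(-2))
})

test_that("scatter matrices match the double-loop oracle and classical limit", {
  set.seed(33)
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3)
  A <- affinity_matrix(X, local_scaling(X, K = 3))
  sc <- local_scatter_matrices(X, y, A)
  ref <- naive_scatter(X, y, A)
  expect_equal(sc$Sw, ref$Sw, tolerance = 1e-10)
  expect_equal(sc$Sb, ref$Sb, tolerance = 1e-10)
  expect_lt(max(abs(sc$Sw - t(sc$Sw))), 1e-10)
  expect_gte(min(eigen(sc$Sw, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)

  # all-ones affinity: Sw reduces to n_l-weighted classical within scatter;
  # with W[i,j] = 1/n_l the assembled matrix IS the classical scatter
  A1 <- matrix(1, 10, 10)
  sc1 <- local_scatter_matrices(X, y, A1)
  expect_equal(sc1$Sw, classical_within_scatter(X, y), tolerance = 1e-10)

  # one sample per class: no same-class pair with i != j -> Sw = 0
  sc2 <- local_scatter_matrices(X[1:2, ], c(1, 2), matrix(1, 2, 2))
  expect_equal(sc2$Sw, matrix(0, 4, 4))
})

test_that("lfda recovers a known discriminative axis", {
  set.seed(34)
  n <- 30
  X <- rbind(cbind(rnorm(n, -5), matrix(rnorm(n * 4), n)),
             cbind(rnorm(n, 5), matrix(rnorm(n * 4), n)))
  y <- rep(1:2, each = n)
  m <- lfda_fit(X, y, r = 1)
  # sampling noise at n = 60, d = 5 caps the attainable alignment near
  # 0.95-0.99 (checked across seeds and both affinity variants)
  expect_gt(abs(m$T[1, 1]) / sqrt(sum(m$T[, 1]^2)), 0.95)
  expect_true(all(diff(m$eigenvalues) <= 1e-8))
})

test_that("eigenpairs satisfy the generalized problem and match dense solve", {
  X6 <- matrix(c(0, 0, 1, 0.1, 0.2, -0.1,
                 5, 1, 6, 1.2, 5.5, 0.8), 6, 2)
  y6 <- c(1, 1, 1, 2, 2, 2)
  m <- lfda_fit(X6, y6, r = 2, K = 3)
  Swr <- m$Sw + diag(m$epsilon, 2)
  # residual of the generalized eigenproblem
  for (k in 1:2) {
    res <- m$Sb %*% m$T[, k] - m$eigenvalues[k] * (Swr %*% m$T[, k])
    expect_lt(max(abs(res)), 1e-8 * max(abs(m$Sb)) + 1e-12)
  }
  # dense oracle: eigen of solve(Swr) %*% Sb
  ev <- eigen(solve(Swr) %*% m$Sb)
  expect_equal(sort(m$eigenvalues), sort(Re(ev$values)), tolerance = 1e-8)
})

test_that("no-signal duplicated classes give a near-null leading eigenvalue", {
  set.seed(35)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y_null <- rep(1:2, 30)            # labels carry no information
  m <- lfda_fit(X, y_null, r = 1)
  perm <- replicate(20, lfda_fit(X, sample(y_null), r = 1)$eigenvalues[1])
  expect_lt(m$eigenvalues[1], max(perm) * 1.5)
})

test_that("transform is the matrix product with shape and conformity checks", {
  set.seed(36)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(1:2, each = 20)
  m <- lfda_fit(X, y, r = 3)
  Z <- lfda_transform(m, X)
  expect_equal(dim(Z), c(40L, 3L))
  expect_equal(Z, X %*% m$T)
  expect_equal(dim(lfda_transform(m, X[1, ])), c(1L, 3L))
  expect_error(lfda_transform(m, X[, 1:5]), "5 columns")
  expect_error(lfda_fit(X, y, r = 7), "smaller r")
})

test_that("rotating the inputs rotates the fitted subspace", {
  set.seed(37)
  n <- 25
  X <- rbind(matrix(rnorm(n * 4), n), sweep(matrix(rnorm(n * 4), n), 2,
                                            c(4, -2, 1, 0), "+"))
  y <- rep(1:2, each = n)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  m1 <- lfda_fit(X, y, r = 2)
  m2 <- lfda_fit(X %*% Q, y, r = 2)
  # compare spanned subspaces via principal angles
  ang <- svd(crossprod(qr.Q(qr(t(Q) %*% m1$T)), qr.Q(qr(m2$T))))$d
  expect_true(all(abs(ang - 1) < 1e-6))
})

test_that("model JSON round trip preserves the transform", {
  set.seed(38)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(1:2, each = 15)
  m <- lfda_fit(X, y, r = 2)
  f <- withr::local_tempfile(fileext = ".json")
  lfda_save(m, f)
  m2 <- lfda_load(f)
  expect_equal(m2$T, m$T, tolerance = 1e-12)
  expect_equal(lfda_transform(m2, X), lfda_transform(m, X), tolerance = 1e-12)
})
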