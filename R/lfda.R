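#' Local scaling bandwidths
#'
#' sigma_i is the Euclidean distance from sample i to its K-th nearest
#' neighbor (self excluded), the Zelnik-Manor/Perona local scale. K = 7 is
#' the value recommended for high-dimensional data and the default
#' throughout. Zero distances (duplicate points) are floored at 1e-12 with a
#' warning.
#'
#' @param X n x d numeric matrix, rows are samples.
#' @param K neighbor index, n >= K + 1.
#' @return Numeric vector of n positive scales.
#' @export
local_scaling <- function(X, K = 7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= K)
    stop("local scaling needs n > K (n = ", n, ", K = ", K,
         "); lower K or add samples")
  D <- as.matrix(dist(X))
  sigma <- unname(apply(D, 1, function(r) sort(r)[K + 1L]))  # self is the 0
  if (any(sigma <= 0)) {
    warning("duplicate samples give zero local scale; floored at 1e-12")
    sigma[sigma <= 0] <- 1e-12
  }
  sigma
}

#' Local-scaling affinity matrix
#'
#' A[i,j] = exp(-||x_i - x_j|| / (sigma_i * sigma_j)) with the unsquared
#' distance as the model prescribes; `variant = "squared"` uses the squared
#' distance of the original local-scaling construction instead. Diagonal is
#' exactly 1 and the matrix is symmetric.
#'
#' @param X n x d numeric matrix.
#' @param sigma n positive local scales, see [local_scaling()].
#' @param variant `"plain"` (unsquared distance, default) or `"squared"`.
#' @return n x n affinity matrix.
#' @export
affinity_matrix <- function(X, sigma, variant = c("plain", "squared")) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  if (any(sigma <= 0)) stop("sigma must be positive")
  D <- as.matrix(dist(X))
  if (variant == "squared") D <- D * D
  A <- exp(-D / tcrossprod(sigma))
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- NULL
  A
}

#' Local within- and between-class scatter matrices
#'
#' Sw = 1/2 sum_{i,j} Ww[i,j] (x_i - x_j)(x_i - x_j)^T, and likewise Sb with
#' Wb, where for same-class pairs (class l, size n_l) Ww[i,j] = A[i,j]/n_l
#' and Wb[i,j] = A[i,j](1/n - 1/n_l), and for cross-class pairs Ww = 0,
#' Wb = 1/n. Assembled via the graph-Laplacian identity
#' 1/2 sum W_ij (x_i-x_j)(x_i-x_j)^T = X^T (D - W) X.
#'
#' @param X n x d numeric matrix.
#' @param y n class indices in 1..c, every class non-empty.
#' @param A n x n affinity matrix, see [affinity_matrix()].
#' @return list(Sw, Sb) of d x d symmetric matrices.
#' @export
local_scatter_matrices <- function(X, y, A) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.integer(y)
  cls <- sort(unique(y))
  counts <- table(factor(y, levels = cls))
  if (any(counts == 0)) stop("every class must have at least one member")
  same <- outer(y, y, "==")
  nl <- as.numeric(counts[match(y, cls)])      # class size of sample i
  Nl <- matrix(nl, n, n)                       # row i's class size
  Ww <- ifelse(same, A / Nl, 0)
  Wb <- ifelse(same, A * (1 / n - 1 / Nl), 1 / n)
  lap <- function(W) {
    S <- crossprod(X, (diag(rowSums(W)) - W) %*% X)
    (S + t(S)) / 2
  }
  list(Sw = lap(Ww), Sb = lap(Wb))
}

#' Fit a local Fisher discriminant transform
#'
#' Maximizes the locality-weighted trace ratio
#' tr((T' Sw T)^{-1} T' Sb T) by taking the top-r generalized eigenvectors
#' of Sb t = lambda (Sw + eps I) t, with ridge eps =
#' 1e-6 * trace(Sw)/d guarding against singular within-class scatter.
#' Columns of T have unit Euclidean norm and their largest-magnitude entry
#' made positive; eigenvalues are returned in descending order. The selected
#' default reduced dimension is r = 10.
#'
#' @param X n x d feature matrix.
#' @param y n class indices in 1..c; needs n > number of classes.
#' @param r target dimension, 1 <= r <= d.
#' @param K local-scaling neighbor index, default 7.
#' @param affinity `"plain"` or `"squared"`, see [affinity_matrix()].
#' @return An object of class `lfda_model`: list(T, eigenvalues, Sw, Sb,
#'   r, K, affinity, epsilon, d).
#' @export
lfda_fit <- function(X, y, r = 10, K = 7, affinity = c("plain", "squared")) {
  affinity <- match.arg(affinity)
  X <- as.matrix(X)
  d <- ncol(X)
  y <- as.integer(y)
  if (r < 1) stop("r must be >= 1")
  if (r > d)
    stop("r = ", r, " exceeds the ", d,
         " available eigenvectors; choose a smaller r")
  if (nrow(X) <= length(unique(y)))
    stop("need more samples than classes to form scatter matrices")
  sigma <- local_scaling(X, K)
  A <- affinity_matrix(X, sigma, affinity)
  sc <- local_scatter_matrices(X, y, A)
  eps <- 1e-6 * sum(diag(sc$Sw)) / d
  if (eps <= 0) eps <- 1e-12
  Swr <- sc$Sw + diag(eps, d)
  U <- chol(Swr)                       # Swr = U'U
  Ui <- backsolve(U, diag(d))
  B <- crossprod(Ui, sc$Sb %*% Ui)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  Tm <- Ui %*% e$vectors[, seq_len(r), drop = FALSE]
  # unit-norm columns, sign fixed by the largest-magnitude entry
  Tm <- apply(Tm, 2, function(t) {
    t <- t / sqrt(sum(t * t))
    if (t[which.max(abs(t))] < 0) -t else t
  })
  Tm <- matrix(Tm, nrow = d)
  structure(list(T = Tm, eigenvalues = e$values[seq_len(r)], Sw = sc$Sw,
                 Sb = sc$Sb, r = as.integer(r), K = as.integer(K),
                 affinity = affinity, epsilon = eps, d = d),
            class = "lfda_model")
}

#' @export
print.lfda_model <- function(x, ...) {
  cat(sprintf("<lfda_model> %d -> %d dims (K = %d, affinity = %s)\n",
              x$d, x$r, x$K, x$affinity))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Project samples with a fitted LFDA transform
#'
#' @param model an `lfda_model`.
#' @param Xnew matrix (or vector) with the model's d columns.
#' @return n x r matrix Z = Xnew T.
#' @export
lfda_transform <- function(model, Xnew) {
  stopifnot(inherits(model, "lfda_model"))
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != model$d)
    stop("Xnew has ", ncol(Xnew), " columns; model expects ", model$d)
  Xnew %*% model$T
}

#' Serialize / restore an LFDA model as JSON
#'
#' Stores the transform, eigenvalues, ridge and fit settings; scatter
#' matrices are not kept.
#'
#' @param model an `lfda_model`.
#' @param path JSON file.
#' @return `path` (save) or the restored `lfda_model` (load).
#' @export
lfda_save <- function(model, path) {
  stopifnot(inherits(model, "lfda_model"))
  jsonlite::write_json(
    list(T = as.vector(model$T), eigenvalues = model$eigenvalues,
         r = model$r, K = model$K, affinity = model$affinity,
         epsilon = model$epsilon, d = model$d),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname lfda_save
#' @param path JSON file written by [lfda_save()].
#' @export
lfda_load <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(T = matrix(j$T, nrow = j$d), eigenvalues = j$eigenvalues,
                 Sw = NULL, Sb = NULL, r = as.integer(j$r),
                 K = as.integer(j$K), affinity = j$affinity,
                 epsilon = j$epsilon, d = as.integer(j$d)),
            class = "lfda_model")
}
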