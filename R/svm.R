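#' RBF kernel matrix
#'
#' K(x, y) = exp(-gamma * ||x - y||^2).
#'
#' @param X n x d matrix.
#' @param Y m x d matrix, defaults to `X`.
#' @param gamma kernel width, > 0.
#' @return n x m kernel matrix.
#' @export
rbf_kernel <- function(X, Y = NULL, gamma) {
  X <- as.matrix(X)
  Y <- if (is.null(Y)) X else as.matrix(Y)
  if (gamma <= 0) stop("gamma must be positive")
  d2 <- outer(rowSums(X * X), rowSums(Y * Y), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

# binary soft-margin RBF SVC via the compiled SMO solver; y in {-1, +1}
svc_fit <- function(X, y, C, gamma, tol = 1e-3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)), length(y) == nrow(X))
  if (length(unique(y)) < 2) stop("binary SVC needs both classes present")
  K <- rbf_kernel(X, gamma = gamma)
  sol <- smo_solve(K, y, C, tol = tol)
  sv <- which(sol$alpha > 1e-12)
  structure(list(X = X[sv, , drop = FALSE], coef = (sol$alpha * y)[sv],
                 sv_index = sv, b = sol$b, gamma = gamma, C = C,
                 train_decision = as.vector(K[, sv, drop = FALSE] %*%
                                              (sol$alpha * y)[sv]) + sol$b),
            class = "svc_model")
}

svc_decision <- function(model, Xnew) {
  Kx <- rbf_kernel(as.matrix(Xnew), model$X, model$gamma)
  as.vector(Kx %*% model$coef) + model$b
}

# Platt sigmoid P(y=1|f) = 1/(1+exp(A f + B)), fitted by the regularized
# Newton iteration of Lin, Lin & Weng (2007) on (decision, label) pairs
platt_fit <- function(decision, y, max_iter = 100) {
  t1 <- sum(y > 0); t0 <- sum(y <= 0)
  hi <- (t1 + 1) / (t1 + 2); lo <- 1 / (t0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0; B <- log((t0 + 1) / (t1 + 1))
  fval <- function(A, B) {
    z <- A * decision + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  f <- fval(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * decision + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- t - p
    w <- p * q
    g1 <- sum(decision * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(decision^2 * w) + 1e-12
    h22 <- sum(w) + 1e-12
    h21 <- sum(decision * w)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    step <- 1
    repeat {
      An <- A + step * dA; Bn <- B + step * dB
      fn <- fval(An, Bn)
      if (fn < f + 1e-4 * step * (g1 * dA + g2 * dB)) {
        A <- An; B <- Bn; f <- fn; break
      }
      step <- step / 2
      if (step < 1e-10) return(c(A = A, B = B))
    }
  }
  c(A = A, B = B)
}

platt_prob <- function(ab, decision) {
  z <- ab[["A"]] * decision + ab[["B"]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

# pairwise coupling (Wu, Lin & Weng 2004, method 2): combine the pairwise
# probabilities r[i,j] = P(class i | i or j) into class probabilities
couple_pairwise <- function(R) {
  c <- nrow(R)
  Q <- matrix(0, c, c)
  for (i in seq_len(c)) {
    Q[i, i] <- sum(R[-i, i]^2)
    for (j in seq_len(c)) if (j != i) Q[i, j] <- -R[j, i] * R[i, j]
  }
  M <- rbind(cbind(Q, 1), c(rep(1, c), 0))
  sol <- tryCatch(solve(M, c(rep(0, c), 1)), error = function(e) NULL)
  p <- if (is.null(sol)) rep(1 / c, c) else sol[seq_len(c)]
  p <- pmax(p, 0)
  p / sum(p)
}

#' Resolve a one-vs-one vote
#'
#' Returns the class with the most pairwise votes; ties go to the tied class
#' that appears first (smallest class index).
#'
#' @param votes numeric vector of per-class vote counts.
#' @return Winning class index.
#' @export
ovo_vote_tiebreak <- function(votes) {
  which.max(votes)  # which.max returns the first maximum
}

#' Fit a one-vs-one multi-class RBF SVM
#'
#' Trains the k(k-1)/2 pairwise soft-margin classifiers; each also gets a
#' Platt sigmoid (fitted on its training decision values) so that class
#' membership probabilities can be formed by pairwise coupling at prediction
#' time.
#'
#' @param X n x d feature matrix.
#' @param y n class indices in 1..c.
#' @param C,gamma SVM regularization and RBF width.
#' @param platt fit Platt sigmoids (disable to skip probability support,
#'   e.g. inside grid-search loops that only need votes).
#' @return An object of class `ovo_svm`.
#' @export
ovo_svm_fit <- function(X, y, C, gamma, platt = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  cls <- sort(unique(y))
  if (length(cls) < 2) stop("need at least two classes")
  pairs <- combn(length(cls), 2)
  models <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- cls[pairs[1, p]]; j <- cls[pairs[2, p]]
    sel <- y %in% c(i, j)
    yb <- ifelse(y[sel] == i, 1, -1)   # class i is the positive class
    m <- svc_fit(X[sel, , drop = FALSE], yb, C, gamma)
    if (platt) m$platt <- platt_fit(m$train_decision, yb)
    m$classes <- c(i, j)
    m
  })
  structure(list(models = models, classes = cls, C = C, gamma = gamma),
            class = "ovo_svm")
}

#' Predict with a one-vs-one RBF SVM
#'
#' @param object an `ovo_svm` model.
#' @param newdata matrix of samples.
#' @param ... unused.
#' @return list with `class` (votes + first-class tie-break), `votes`
#'   (n x c), and `prob` (n x c pairwise-coupled class probabilities).
#' @export
predict.ovo_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  n <- nrow(newdata)
  cidx <- object$classes
  c <- length(cidx)
  votes <- matrix(0, n, c, dimnames = list(NULL, cidx))
  with_prob <- !is.null(object$models[[1]]$platt)
  Rcube <- if (with_prob) array(0.5, dim = c(n, c, c))
  for (m in object$models) {
    f <- svc_decision(m, newdata)
    i <- match(m$classes[1], cidx); j <- match(m$classes[2], cidx)
    votes[, i] <- votes[, i] + (f > 0)
    votes[, j] <- votes[, j] + (f <= 0)
    if (with_prob) {
      pij <- platt_prob(m$platt, f)
      Rcube[, i, j] <- pij
      Rcube[, j, i] <- 1 - pij
    }
  }
  prob <- if (with_prob) {
    pr <- t(vapply(seq_len(n), function(s) couple_pairwise(Rcube[s, , ]),
                   numeric(c)))
    colnames(pr) <- cidx
    pr
  }
  list(class = cidx[apply(votes, 1, ovo_vote_tiebreak)], votes = votes,
       prob = prob)
}
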