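#' Integrated (cumulative-sum) profile of a PSSM column
#'
#' DCCA operates on the running cumulative sums of each normalized column,
#' treated as a non-stationary series: M_k = sum_{i<=k} m_i.
#'
#' @param col numeric vector (one normalized PSSM column).
#' @return Numeric vector of the same length.
#' @export
integrated_profile <- function(col) {
  if (!length(col)) stop("empty column")
  cumsum(as.numeric(col))
}

# residuals of per-window OLS line fits against position index k, for all
# L-S overlapping windows of S+1 points (stride 1, fixed by the L-S window
# count of the segment average). Returns an (S+1) x (L-S) matrix.
.window_residuals <- function(M, S) {
  L <- length(M)
  if (S < 1L || S > L - 1L)
    stop("window parameter S = ", S, " exceeds profile length ", L,
         " (need 1 <= S <= L-1)")
  w <- S + 1L
  nw <- L - S
  idx <- outer(seq_len(w), 0:(nw - 1L), "+")
  W <- matrix(M[idx], nrow = w)
  xc <- seq_len(w) - (w + 1) / 2            # centered position index
  sxx <- sum(xc * xc)
  slope <- as.vector(crossprod(xc, W)) / sxx
  W - rep(colMeans(W), each = w) - outer(xc, slope)
}

#' Detrended covariance of one window
#'
#' For the window of S+1 points starting at position i, each integrated
#' profile gets its own ordinary-least-squares straight-line fit against the
#' position index; the statistic is the mean product of the two residual
#' series over the window. With `N = M` this is the (non-negative) detrended
#' variance of the window.
#'
#' @param M,N integrated profiles of equal length L (see
#'   [integrated_profile()]).
#' @param S window parameter; the window spans positions i..i+S.
#' @param i 1-based start position, 1 <= i <= L-S.
#' @return Scalar f2_xy(S, i).
#' @export
window_detrended_cov <- function(M, N, S, i) {
  L <- length(M)
  if (length(N) != L) stop("profiles differ in length")
  S <- as.integer(S); i <- as.integer(i)
  if (S < 1L || S >= L) stop("window parameter S out of range")
  if (i < 1L || i > L - S) stop("window start index i = ", i, " out of range")
  k <- i:(i + S)
  fit <- function(v) stats::lm.fit(cbind(1, k), v)$residuals
  mean(fit(M[k]) * fit(N[k]))
}

#' Segment-averaged detrended covariance
#'
#' Mean of [window_detrended_cov()] over all L-S overlapping windows.
#'
#' @inheritParams window_detrended_cov
#' @return Scalar f2_xy(S).
#' @export
dcca_variance_profile <- function(M, N, S) {
  L <- length(M)
  if (length(N) != L) stop("profiles differ in length")
  RM <- .window_residuals(M, S)
  RN <- .window_residuals(N, S)
  sum(RM * RN) / length(RM)
}

#' Detrended cross-correlation coefficient of two columns
#'
#' rho = f2_xy(S) / sqrt(f2_xx(S) * f2_yy(S)), guaranteed in [-1, 1] by
#' Cauchy-Schwarz over the concatenated window residuals. A zero denominator
#' (a profile exactly linear inside every window) yields 0 with a warning,
#' 0 being the no-correlation value.
#'
#' @param colA,colB normalized PSSM columns of equal length L.
#' @param S window parameter, 1 <= S <= L-1.
#' @return Scalar in [-1, 1].
#' @export
dcca_coefficient <- function(colA, colB, S) {
  if (length(colA) != length(colB)) stop("columns differ in length")
  MA <- integrated_profile(colA)
  MB <- integrated_profile(colB)
  RA <- .window_residuals(MA, S)
  RB <- .window_residuals(MB, S)
  den <- sqrt(sum(RA * RA) * sum(RB * RB))
  if (den == 0) {
    warning("zero detrended variance; returning rho = 0")
    return(0)
  }
  max(-1, min(1, sum(RA * RB) / den))
}

#' DCCA coefficient features of a normalized PSSM
#'
#' Computes rho for all choose(20, 2) = 190 unordered column pairs, ordered
#' (1,2), (1,3), ..., (19,20) over the PSI-BLAST residue order. The selected
#' default window parameter is S = 40; a protein must satisfy L >= S + 1.
#'
#' @param p a `norm_pssm` object or numeric L x 20 matrix.
#' @param S window parameter.
#' @return Named numeric vector of length 190 (`dcca_<res1><res2>`), every
#'   entry in [-1, 1].
#' @export
dcca_features <- function(p, S = 40) {
  v <- .pssm_values(p)
  L <- nrow(v)
  S <- as.integer(S)
  if (S < 1L || S > L - 1L)
    stop("protein '", .pssm_id(p), "' has length ", L,
         " but the DCCA window parameter S = ", S, " requires length >= S+1")
  # stack each column's window residuals; all 190 pair statistics are then
  # entries of one cross-product matrix
  R <- vapply(seq_len(20L),
              function(j) as.vector(.window_residuals(cumsum(v[, j]), S)),
              numeric((S + 1L) * (L - S)))
  F2 <- crossprod(R) / nrow(R)
  d <- sqrt(diag(F2))
  pairs <- combn(20L, 2L)
  den <- d[pairs[1, ]] * d[pairs[2, ]]
  num <- F2[cbind(pairs[1, ], pairs[2, ])]
  if (any(den == 0)) {
    warning("zero detrended variance in protein '", .pssm_id(p),
            "'; affected rho set to 0")
    num[den == 0] <- 0
    den[den == 0] <- 1
  }
  res <- pssm_residues()
  setNames(pmax(-1, pmin(1, num / den)),
           paste0("dcca_", res[pairs[1, ]], res[pairs[2, ]]))
}
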