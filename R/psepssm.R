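#' Per-column means of a normalized PSSM
#'
#' The composition part of the pseudo-PSSM descriptor: for each residue
#' column j, the mean normalized score over all L positions.
#'
#' @param p a `norm_pssm` object or numeric L x 20 matrix.
#' @return Named numeric vector of 20 column means.
#' @export
column_means <- function(p) {
  v <- .pssm_values(p)
  setNames(colMeans(v), paste0("pse_mean_", pssm_residues()))
}

#' Lag squared-difference terms of a normalized PSSM
#'
#' The sequence-order part of the pseudo-PSSM descriptor: for lag g and each
#' column j,
#' theta_j^g = (1/(L-g)) * sum_{i=1}^{L-g} (P[i,j] - P[i+g,j])^2.
#'
#' @param p a `norm_pssm` object or numeric L x 20 matrix.
#' @param g lag, 1 <= g < L.
#' @return Named numeric vector of 20 non-negative values.
#' @export
lag_theta <- function(p, g) {
  v <- .pssm_values(p)
  L <- nrow(v)
  g <- as.integer(g)
  if (g < 1L) stop("lag must be >= 1")
  if (g >= L)
    stop("lag ", g, " exceeds sequence length ", L, " for protein '",
         .pssm_id(p), "'")
  d <- v[seq_len(L - g), , drop = FALSE] - v[g + seq_len(L - g), , drop = FALSE]
  setNames(colMeans(d * d), paste0("pse_theta", g, "_", pssm_residues()))
}

#' Pseudo-PSSM feature vector
#'
#' Concatenates the 20 column means with the lag terms for g = 1..xi, giving
#' a vector of length 20 + 20*xi. `xi = 0` yields the means-only 20-vector
#' (the reading used for lag-free parameter sweeps). The selected default is
#' xi = 3, i.e. an 80-dimensional descriptor.
#'
#' @param p a `norm_pssm` object or numeric L x 20 matrix.
#' @param xi maximum lag, 0 <= xi < L.
#' @return Named numeric vector of length 20 + 20*xi.
#' @export
psepssm_features <- function(p, xi = 3) {
  xi <- as.integer(xi)
  if (xi < 0L) stop("xi must be >= 0")
  out <- column_means(p)
  if (xi > 0L)
    out <- c(out, unlist(lapply(seq_len(xi), function(g) lag_theta(p, g))))
  out
}
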