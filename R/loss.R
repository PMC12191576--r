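# residuals r_k = Y_k - sum_{j=0}^{min(k-1, L)} Phi_j Y_{k-j}
cg_residuals <- function(Y, phi) {
  n <- nrow(Y); d <- ncol(Y)
  L <- dim(phi)[3] - 1L
  R <- Y - Y %*% t(matrix(phi[, , 1], d, d))
  if (L >= 1) for (j in seq_len(min(L, n - 1L))) {
    R[(j + 1L):n, ] <- R[(j + 1L):n, , drop = FALSE] -
      Y[seq_len(n - j), , drop = FALSE] %*% t(matrix(phi[, , j + 1L], d, d))
  }
  R
}

#' Quasi-likelihood loss of the coarse-grained Hawkes model
#'
#' The AR(infinity)-based loss
#' `L_n = sum_k r_k^T diag(lambda_hat)^{-1} r_k - 2 n log|I - Phi_0|` with
#' residuals `r_k = Y_k - sum_{j=0}^{k-1} Phi_j Y_{k-j}` on mean-centred
#' counts `Y_k = X_k - lambda_hat`; the log-determinant term penalises the
#' trivial solution `Phi_k = delta_k0 I`. Cost `O(n L d^2)`.
#'
#' @param Y Mean-centred count matrix (`n x d`), i.e. counts minus the
#'   empirical mean per component.
#' @param ck A `coarse_kernel` giving `Phi_0..Phi_L` at the data's bin
#'   width.
#' @param lam_hat Empirical mean counts per bin (entrywise > 0).
#' @return Scalar loss; a large finite barrier value (not `NaN`) when
#'   `|I - Phi_0| <= 0`.
#' @export
cg_loss <- function(Y, ck, lam_hat) {
  Y <- as_count_matrix(Y)
  if (any(lam_hat <= 0))
    stop("empirical mean has a zero entry; use a longer series or drop the silent component",
         call. = FALSE)
  d <- ncol(Y); n <- nrow(Y)
  Phi0 <- matrix(ck$phi[, , 1], d, d)
  det0 <- det(diag(d) - Phi0)
  if (!is.finite(det0) || det0 <= 0) {
    return(1e10 * (1 + max(0, -det0)))  # barrier branch
  }
  R <- cg_residuals(Y, ck$phi)
  sum((R * R) %*% (1 / lam_hat)) - 2 * n * log(det0)
}

#' Log-likelihood of the binned-Poisson approximation
#'
#' Conditional intensities `lambda_n = mu dt + sum_{k>=1} Phi(k dt) dt
#' X_{n-k}` (sampled kernel, no intra-bin term) with counts conditionally
#' Poisson: `loglik = sum_{k,j} X_jk log lambda_jk - lambda_jk`.
#'
#' @param x A `bin_counts` object.
#' @param mu Baseline intensity vector (events per unit time).
#' @param spec A [kernel_spec].
#' @param tol Sampled-kernel truncation tolerance.
#' @return Scalar log-likelihood (`-Inf` guarded by a barrier when an
#'   intensity is nonpositive with a positive count).
#' @export
binned_poisson_loglik <- function(x, mu, spec, tol = 1e-10) {
  dt <- bin_dt(x)
  m <- as_count_matrix(x)
  ck <- sampled_kernel(spec, dt, tol)
  lam <- poisson_intensities(m, mu, ck)
  if (any(lam <= 0)) {
    bad <- lam <= 0 & m > 0
    if (any(bad)) return(-1e10 * (1 + sum(bad)))
    lam <- pmax(lam, 1e-12)
  }
  sum(m * log(lam) - lam)
}

# lambda_n = mu dt + sum_{k=1}^{L} Phi_k X_{n-k}, vectorised over bins
poisson_intensities <- function(m, mu, ck) {
  n <- nrow(m); d <- ncol(m)
  if (length(mu) == 1) mu <- rep(mu, d)
  lam <- matrix(rep(mu * ck$dt, each = n), n, d)
  L <- ck$L
  if (L >= 1) for (k in seq_len(min(L, n - 1L))) {
    lam[(k + 1L):n, ] <- lam[(k + 1L):n, , drop = FALSE] +
      m[seq_len(n - k), , drop = FALSE] %*% t(matrix(ck$phi[, , k + 1L], d, d))
  }
  lam
}

#' Whittle (spectral) loss on the coarse-grained spectrum
#'
#' Experimental spectral analogue of [cg_loss()]:
#' `sum_m [ Xhat_m^H F_cg(omega_m)^{-1} Xhat_m + log |F_cg(omega_m)| ]` over
#' the Fourier frequencies, with `Xhat_m` the normalised mean-centred DFT.
#' For long series this approximates the quasi-likelihood loss up to
#' affine terms.
#'
#' @param x A `bin_counts` object.
#' @param ck A `coarse_kernel` at the data's bin width.
#' @param lam Stationary mean per bin used in the spectrum (defaults to the
#'   empirical mean).
#' @return Scalar loss.
#' @export
whittle_loss <- function(x, ck, lam = NULL) {
  m <- as_count_matrix(x)
  n <- nrow(m); d <- ncol(m)
  lam <- lam %||% colMeans(m)
  Yc <- sweep(m, 2, colMeans(m))
  Z <- mvfft(Yc) / sqrt(2 * pi * n)
  ms <- seq_len(n - 1L)
  omega <- 2 * pi * ms / n
  P <- coarse_transfer(ck, omega)
  Fgrid <- bartlett_sandwich(P, lam)
  val <- 0
  for (k in seq_along(ms)) {
    Fm <- matrix(Fgrid[, , k], d, d)
    z <- Z[ms[k] + 1L, ]
    q <- Re(Conj(z) %*% solve(Fm, z))
    val <- val + as.numeric(q) + log(Re(cdet(Fm)))
  }
  val
}
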