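#' Stationary mean of the coarse-grained count process
#'
#' `lambda = (I - A)^{-1} mu dt`, counts per bin, where `A` is the
#' branching matrix of the coarse kernel (equal to the continuous-time
#' branching matrix by mass conservation).
#'
#' @param mu Baseline intensity vector (events per unit time).
#' @param ck A `coarse_kernel`.
#' @return Numeric vector of expected counts per bin.
#' @export
stationary_mean <- function(mu, ck) {
  bm <- branching_matrix(ck)
  if (!bm$stationary)
    stop(sprintf("nonstationary kernel: branching spectral radius %.3f >= 1", bm$radius),
         call. = FALSE)
  if (length(mu) == 1) mu <- rep(mu, ck$d)
  as.numeric(solve(diag(ck$d) - bm$A, mu)) * ck$dt
}

#' Effective (moving-average) kernels of the stationary process
#'
#' The stationary count process admits an MA(infinity) representation with
#' matrix weights `Psi_k = sum_j (Phi^(*j))_k` (the Neumann series of the
#' coarse kernel under discrete convolution). They satisfy the recursion
#' `Psi_0 = (I - Phi_0)^{-1}`,
#' `Psi_k = (I - Phi_0)^{-1} sum_{j=1}^{k} Phi_j Psi_{k-j}`, and
#' `sum_k Psi_k = (I - A)^{-1}` up to truncation.
#'
#' @param ck A `coarse_kernel`.
#' @param L Highest lag to return; if `NULL`, extended until the Frobenius
#'   norm of `Psi_L` falls below `tol`.
#' @param tol Truncation tolerance for automatic `L`.
#' @return An `effective_kernel`: list with `psi` (`d x d x (L+1)` array),
#'   `dt`, `d`.
#' @export
effective_kernels <- function(ck, L = NULL, tol = 1e-10) {
  d <- ck$d
  Phi0 <- matrix(ck$phi[, , 1], d, d)
  if (spectral_radius(Phi0) >= 1)
    stop("spectral radius of Phi_0 >= 1; (I - Phi_0) is not invertible", call. = FALSE)
  M0 <- solve(diag(d) - Phi0)
  Lphi <- ck$L
  auto <- is.null(L)
  Lmax <- if (auto) 100000L else L
  psi <- vector("list", 64)
  psi[[1]] <- M0
  k <- 0L
  repeat {
    k <- k + 1L
    if (k > Lmax) { k <- k - 1L; break }
    acc <- matrix(0, d, d)
    for (j in seq_len(min(k, Lphi))) {
      acc <- acc + matrix(ck$phi[, , j + 1L], d, d) %*% psi[[k - j + 1L]]
    }
    pk <- M0 %*% acc
    if (length(psi) < k + 1L) psi <- c(psi, vector("list", length(psi)))
    psi[[k + 1L]] <- pk
    if (auto && sqrt(sum(pk^2)) < tol && k >= Lphi) break
  }
  arr <- array(0, c(d, d, k + 1L))
  for (l in 0:k) arr[, , l + 1L] <- psi[[l + 1L]]
  structure(list(psi = arr, d = d, dt = ck$dt, L = k),
            class = "effective_kernel")
}

#' One-step conditional moments given bin-count history
#'
#' Conditional mean `lambda*_n = (I - Phi_0)^{-1} (mu dt + sum_{k>=1}
#' Phi_k X_{n-k})` and conditional covariance
#' `(I - Phi_0)^{-1} diag(lambda*_n) (I - Phi_0^T)^{-1}`. Intra-bin
#' excitation (`Phi_0`) makes the covariance nondiagonal and its diagonal
#' exceed the mean (overdispersion); with `Phi_0 = 0` the counts are
#' conditionally independent Poisson.
#'
#' @param ck A `coarse_kernel`.
#' @param mu Baseline intensity vector (events per unit time).
#' @param history Matrix of past counts, one row per bin, oldest first; the
#'   last row is bin `n - 1`. May have zero rows.
#' @return List with `mean` and `covariance`.
#' @export
conditional_moments <- function(ck, mu, history = NULL) {
  d <- ck$d
  if (length(mu) == 1) mu <- rep(mu, d)
  Phi0 <- matrix(ck$phi[, , 1], d, d)
  if (spectral_radius(Phi0) >= 1)
    stop("spectral radius of Phi_0 >= 1", call. = FALSE)
  drive <- mu * ck$dt
  if (!is.null(history) && nrow(as_count_matrix(history)) > 0) {
    H <- as_count_matrix(history)
    nh <- nrow(H)
    for (k in seq_len(min(nh, ck$L))) {
      drive <- drive + matrix(ck$phi[, , k + 1L], d, d) %*% H[nh - k + 1L, ]
    }
  }
  M0 <- solve(diag(d) - Phi0)
  m <- as.numeric(M0 %*% drive)
  V <- M0 %*% diag(m, d) %*% t(M0)
  list(mean = m, covariance = V)
}

#' Stationary autocovariances of the coarse-grained process
#'
#' `R_j = Cov(X_n, X_{n+j}) = sum_{l} Psi_l diag(lambda) Psi_{l+j}^T`,
#' truncated at the effective-kernel cutoff; `R_{-j} = R_j^T` by
#' construction.
#'
#' @param ek An `effective_kernel`.
#' @param lam Stationary mean vector (counts per bin), e.g. from
#'   [stationary_mean()].
#' @param J Highest lag.
#' @return A `stationary_moments` object: list with `lam` and `R`
#'   (`d x d x (J+1)` array for lags `0..J`).
#' @export
autocovariance <- function(ek, lam, J) {
  d <- ek$d
  Lpsi <- ek$L
  D <- diag(lam, d)
  R <- array(0, c(d, d, J + 1L))
  # precompute Psi_l diag(lam)
  PD <- array(0, c(d, d, Lpsi + 1L))
  for (l in 0:Lpsi) PD[, , l + 1L] <- matrix(ek$psi[, , l + 1L], d, d) %*% D
  for (j in 0:J) {
    acc <- matrix(0, d, d)
    if (j <= Lpsi) {
      for (l in 0:(Lpsi - j)) {
        acc <- acc + matrix(PD[, , l + 1L], d, d) %*% t(matrix(ek$psi[, , l + j + 1L], d, d))
      }
    }
    R[, , j + 1L] <- acc
  }
  structure(list(lam = lam, R = R, d = d, J = J, dt = ek$dt),
            class = "stationary_moments")
}

#' Empirical autocovariances of a bin-count series
#'
#' `R_j = n^{-1} sum_{k=1}^{n-j} (X_k - xbar)(X_{k+j} - xbar)^T`.
#'
#' @param x A `bin_counts` object (or count matrix).
#' @param J Highest lag.
#' @return A `stationary_moments` object with the empirical mean in `lam`.
#' @export
empirical_autocovariance <- function(x, J) {
  m <- as_count_matrix(x)
  n <- nrow(m); d <- ncol(m)
  stopifnot(J < n)
  xbar <- colMeans(m)
  Yc <- sweep(m, 2, xbar)
  R <- array(0, c(d, d, J + 1L))
  for (j in 0:J) {
    R[, , j + 1L] <- crossprod(Yc[seq_len(n - j), , drop = FALSE],
                               Yc[(1 + j):n, , drop = FALSE]) / n
  }
  structure(list(lam = xbar, R = R, d = d, J = J,
                 dt = attr(x, "dt")),
            class = "stationary_moments")
}

#' @export
print.stationary_moments <- function(x, ...) {
  cat(sprintf("<stationary_moments> d = %d, lags 0..%d\n", x$d, x$J))
  cat("mean (counts/bin):", signif(x$lam, 5), "\n")
  invisible(x)
}

#' Tidy stationary moments into a long tibble
#' @param x A `stationary_moments` object.
#' @param ... Unused.
#' @export
tidy.stationary_moments <- function(x, ...) {
  d <- x$d; J <- x$J
  tibble::tibble(
    lag = rep(0:J, each = d * d),
    i = rep(rep(seq_len(d), d), J + 1L),
    j = rep(rep(seq_len(d), each = d), J + 1L),
    value = as.vector(x$R)
  )
}
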