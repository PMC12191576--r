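new_cg_spectrum <- function(omega, F, label, dt = NA_real_, extra = list()) {
  structure(c(list(omega = omega, F = F, d = dim(F)[1], label = label, dt = dt),
              extra),
            class = "cg_spectrum")
}

#' @export
print.cg_spectrum <- function(x, ...) {
  cat(sprintf("<cg_spectrum> label = %s, d = %d, %d frequencies\n",
              x$label, x$d, length(x$omega)))
  invisible(x)
}

#' Tidy a spectral grid into a long tibble
#'
#' @param x A `cg_spectrum`.
#' @param ... Unused.
#' @return Tibble with columns `omega`, `i`, `j`, `re`, `im`, `label`.
#' @export
tidy.cg_spectrum <- function(x, ...) {
  d <- x$d; nw <- length(x$omega)
  tibble::tibble(
    omega = rep(x$omega, each = d * d),
    i = rep(rep(seq_len(d), d), nw),
    j = rep(rep(seq_len(d), each = d), nw),
    re = as.vector(Re(x$F)),
    im = as.vector(Im(x$F)),
    label = x$label
  )
}

# sandwich (1/2pi) (I - P(-w))^{-1} diag(lam) (I - P(w)^T)^{-1} for a
# complex transfer array P[d,d,nw]
bartlett_sandwich <- function(P, lam) {
  d <- dim(P)[1]; nw <- dim(P)[3]
  D <- diag(lam, d)
  out <- array(0 + 0i, c(d, d, nw))
  I <- diag(d)
  for (w in seq_len(nw)) {
    Pw <- matrix(P[, , w], d, d)
    out[, , w] <- solve(I - Conj(Pw), D) %*% solve(I - t(Pw))
  }
  out / (2 * pi)
}

# transfer function Phi-hat(omega) = sum_k Phi_k e^{-i omega k}
coarse_transfer <- function(ck, omega) {
  d <- ck$d
  P <- array(0 + 0i, c(d, d, length(omega)))
  for (k in 0:ck$L) {
    Pk <- matrix(ck$phi[, , k + 1L], d, d)
    if (all(Pk == 0)) next
    P <- P + outer(Pk, exp(-1i * omega * k))
  }
  P
}

#' Spectral density of the coarse-grained Hawkes process
#'
#' Evaluates `F(omega) = (1/2pi) (I - Phi^(-omega))^{-1} diag(lambda)
#' (I - Phi^T(omega))^{-1}` with `Phi^(omega) = sum_k Phi_k e^{-i omega k}`
#' (truncated at the kernel cutoff). Frequencies are in radians per bin on
#' `[-pi, pi]`; the matrix at each frequency is Hermitian positive
#' semidefinite and the grid is the Fourier pair of the autocovariances.
#'
#' @param ck A `coarse_kernel`.
#' @param lam Stationary mean vector (counts per bin); see
#'   [stationary_mean()].
#' @param omega Frequency grid in radians per bin.
#' @return A `cg_spectrum` with label `"cg"`.
#' @export
spectral_density_cg <- function(ck, lam, omega = default_omega()) {
  P <- coarse_transfer(ck, omega)
  new_cg_spectrum(omega, bartlett_sandwich(P, lam), "cg", dt = ck$dt)
}

#' Default frequency grid on `[-pi, pi]`
#' @param n Number of grid points (odd keeps 0 in the grid).
#' @export
default_omega <- function(n = 257) seq(-pi, pi, length.out = n)

#' Bartlett spectral density of the continuous-time Hawkes process
#'
#' `F(nu) = (1/2pi) (I - Phi~(-nu))^{-1} diag(lambda*) (I - Phi~(nu)^T)^{-1}`
#' where `Phi~` is the Fourier transform of the excitation kernel matrix and
#' `lambda*` the stationary intensity. Units: events^2 per unit time per
#' radian.
#'
#' @param model A [hawkes_model].
#' @param nu Frequency grid in radians per unit time.
#' @return A `cg_spectrum` with label `"hawkes_continuous"`.
#' @export
spectral_density_hawkes <- function(model, nu) {
  lam_star <- stationary_intensity(model)
  P <- kernel_fourier(model$kernel, nu)
  new_cg_spectrum(nu, bartlett_sandwich(P, lam_star), "hawkes_continuous")
}

# F_hw evaluated at many frequencies, vectorised for d <= 2
hawkes_spectrum_values <- function(spec, lam_star, nu) {
  d <- spec$d
  P <- kernel_fourier(spec, nu)
  if (d == 1) {
    p <- P[1, 1, ]
    F <- array(lam_star[1] / (Mod(1 - p)^2 * 2 * pi), c(1, 1, length(nu)))
    return(F)
  }
  if (d == 2) {
    # closed-form inverse of I - Conj(P) per frequency
    a <- 1 - Conj(P[1, 1, ]); b <- -Conj(P[1, 2, ])
    cc <- -Conj(P[2, 1, ]); dd <- 1 - Conj(P[2, 2, ])
    det <- a * dd - b * cc
    i11 <- dd / det; i12 <- -b / det; i21 <- -cc / det; i22 <- a / det
    l1 <- lam_star[1]; l2 <- lam_star[2]
    # M = inv %*% diag(lam); F = M %*% Conj(t(inv)) / 2pi
    m11 <- i11 * l1; m12 <- i12 * l2
    m21 <- i21 * l1; m22 <- i22 * l2
    F <- array(0 + 0i, c(2, 2, length(nu)))
    F[1, 1, ] <- m11 * Conj(i11) + m12 * Conj(i12)
    F[1, 2, ] <- m11 * Conj(i21) + m12 * Conj(i22)
    F[2, 1, ] <- m21 * Conj(i11) + m22 * Conj(i12)
    F[2, 2, ] <- m21 * Conj(i21) + m22 * Conj(i22)
    return(F / (2 * pi))
  }
  bartlett_sandwich(P, lam_star)
}

#' Spectral density of the binned Hawkes process
#'
#' The bin-count sequence of a Hawkes process is the point process filtered
#' by the bin indicator and sampled, so its spectrum is the aliased,
#' window-weighted Bartlett spectrum
#' `F_bin(omega) = (1/dt) sum_m F_hw(nu_m) |W(nu_m)|^2`,
#' `nu_m = (omega + 2 pi m)/dt`, with `|W(nu)|^2 = dt^2 sinc^2(nu dt / 2)`.
#' The flat high-frequency part `diag(lambda*)/2pi` is summed exactly
#' (`sum_m |W|^2 = dt^2`); the remainder decays as `m^-3` and is summed
#' adaptively until a block contributes less than `tol`.
#'
#' @param model A [hawkes_model] (exponential or gamma kernels use
#'   closed-form transforms; other families fall back to quadrature and are
#'   slow here).
#' @param dt Bin width.
#' @param omega Frequency grid in radians per bin.
#' @param tol Truncation tolerance of the aliasing sum.
#' @param max_alias Cap on the number of alias blocks.
#' @return A `cg_spectrum` with label `"hawkes_binned"`, units counts^2 per
#'   bin per radian.
#' @export
spectral_density_binned_hawkes <- function(model, dt, omega = default_omega(),
                                           tol = 1e-8, max_alias = 2^16) {
  lam_star <- stationary_intensity(model)
  d <- model$d
  spec <- model$kernel
  nw <- length(omega)
  Finf <- diag(lam_star, d) / (2 * pi)
  sinc2 <- function(x) ifelse(abs(x) < 1e-8, 1, (sin(x) / x)^2)
  acc <- array(0 + 0i, c(d, d, nw))
  add_block <- function(ms) {
    # returns the summed contribution of alias indices ms (vector) for all omega
    blk <- array(0 + 0i, c(d, d, nw))
    for (w in seq_len(nw)) {
      nu <- (omega[w] + 2 * pi * ms) / dt
      Fv <- hawkes_spectrum_values(spec, lam_star, nu)
      wgt <- dt^2 * sinc2(nu * dt / 2)
      Fc <- sweep(Fv - array(Finf, c(d, d, length(nu))), 3, wgt, `*`)
      blk[, , w] <- apply(Fc, c(1, 2), sum)
    }
    blk / dt
  }
  K0 <- 32L
  acc <- add_block(-K0:K0)
  K <- K0
  repeat {
    if (K >= max_alias) break
    K2 <- min(max_alias, K * 4L)
    ms <- c(-(K2):-(K + 1L), (K + 1L):K2)
    blk <- add_block(ms)
    acc <- acc + blk
    if (max(Mod(blk)) < tol) { K <- K2; break }
    K <- K2
  }
  F <- acc + array(Finf * dt, c(d, d, nw))
  new_cg_spectrum(omega, F, "hawkes_binned", dt = dt, extra = list(K_alias = K))
}

#' Spectral density of the binned-Poisson approximation
#'
#' The binned-Poisson model drives conditionally Poisson counts with the
#' sampled kernel `Phi_k^po = Phi(k dt) dt` for `k >= 1` (no intra-bin
#' term). Its residual sequence is white with variance `diag(lambda_po)`,
#' so the spectrum is the same sandwich form as the coarse-grained model
#' with `Phi_0 = 0` and mean from the sampled branching matrix.
#'
#' @inheritParams spectral_density_binned_hawkes
#' @param tol Tail tolerance of the sampled-kernel truncation.
#' @return A `cg_spectrum` with label `"poisson_binned"`.
#' @export
spectral_density_binned_poisson <- function(model, dt, omega = default_omega(),
                                            tol = 1e-10) {
  ck <- sampled_kernel(model$kernel, dt, tol)
  bm <- branching_matrix(ck)
  if (!bm$stationary)
    stop("sampled kernel is nonstationary at this bin width", call. = FALSE)
  lam_po <- as.numeric(solve(diag(model$d) - bm$A, model$mu)) * dt
  P <- coarse_transfer(ck, omega)
  new_cg_spectrum(omega, bartlett_sandwich(P, lam_po), "poisson_binned", dt = dt)
}

# sampled kernel of the binned-Poisson generative model: Phi_k = Phi(k dt) dt
# for k >= 1, Phi_0 = 0
sampled_kernel <- function(spec, dt, tol = 1e-10, max_lag = 1e5) {
  d <- spec$d
  L <- 8L
  repeat {
    tailm <- 0
    for (i in seq_len(d)) for (j in seq_len(d)) {
      if (spec$alpha[i, j] == 0) next
      # bound the discarded tail sum_{k>L} phi(k dt) dt by the integral tail
      tailm <- max(tailm, spec$alpha[i, j] - kernel_cumulative(spec, i, j, L * dt) +
                     kernel_eval(spec, i, j, L * dt) * dt)
    }
    if (tailm < tol || L >= max_lag) break
    L <- min(max_lag, L * 4L)
  }
  phi <- array(0, c(d, d, L + 1L))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (spec$alpha[i, j] == 0) next
    phi[i, j, 2:(L + 1L)] <- kernel_eval(spec, i, j, (1:L) * dt) * dt
  }
  tail_mass <- matrix(0, d, d)
  new_coarse_kernel(d, dt, phi, tail_mass, apply(phi, c(1, 2), sum))
}

#' Spectral information loss between two spectra
#'
#' `(1/4pi) int_{-pi}^{pi} log( |F_ref(omega)| / |F_approx(omega)| ) domega`
#' by trapezoidal quadrature over the shared grid: the gap in maximum
#' entropy rates between the two second-order structures. Zero when the
#' grids coincide.
#'
#' @param F_ref,F_approx `cg_spectrum` objects on identical frequency grids.
#' @return Scalar information loss (nats per bin).
#' @export
information_loss <- function(F_ref, F_approx) {
  stopifnot(length(F_ref$omega) == length(F_approx$omega),
            max(abs(F_ref$omega - F_approx$omega)) < 1e-12)
  det_of <- function(S) {
    vapply(seq_along(S$omega), function(w) {
      dv <- Re(cdet(matrix(S$F[, , w], S$d, S$d)))
      if (dv <= 1e-300) stop("nonpositive spectral determinant", call. = FALSE)
      dv
    }, numeric(1))
  }
  lr <- log(det_of(F_ref)) - log(det_of(F_approx))
  w <- F_ref$omega
  trap <- sum(diff(w) * (head(lr, -1) + tail(lr, -1)) / 2)
  trap / (4 * pi)
}

#' Cross-periodogram of a bin-count series
#'
#' Mean-centred DFT-based periodogram
#' `I(omega_m) = Xhat_m Xhat_m^H`, `Xhat_m = (2 pi n)^{-1/2} sum_k (X_k -
#' xbar) e^{-2 pi i k m / n}`, on the positive Fourier frequencies. With
#' `segments > 1` the series is split and the segment periodograms are
#' averaged (Welch), and the segment spread is retained for confidence
#' bands.
#'
#' @param x A `bin_counts` object or count matrix.
#' @param segments Number of equal-length segments to average.
#' @return A `cg_spectrum` with label `"empirical"`; when averaged, carries
#'   `n_seg` and the across-segment standard error array `se`.
#' @export
periodogram <- function(x, segments = 1) {
  m <- as_count_matrix(x)
  n_tot <- nrow(m); d <- ncol(m)
  nseg <- floor(n_tot / segments)
  stopifnot(nseg >= 8)
  per_seg <- vector("list", segments)
  for (s in seq_len(segments)) {
    seg <- m[((s - 1) * nseg + 1):(s * nseg), , drop = FALSE]
    Yc <- sweep(seg, 2, colMeans(seg))
    Z <- mvfft(Yc) / sqrt(2 * pi * nseg)
    nf <- floor((nseg - 1) / 2)
    I <- array(0 + 0i, c(d, d, nf))
    for (mm in seq_len(nf)) {
      zr <- Z[mm + 1L, ]
      I[, , mm] <- zr %*% Conj(t(zr))
    }
    per_seg[[s]] <- I
  }
  omega <- 2 * pi * seq_len(dim(per_seg[[1]])[3]) / nseg
  Fbar <- Reduce(`+`, per_seg) / segments
  extra <- list(n_seg = segments)
  if (segments > 1) {
    sq <- Reduce(`+`, lapply(per_seg, function(I) Mod(I - Fbar)^2)) / (segments - 1)
    extra$se <- sqrt(sq / segments)
  }
  new_cg_spectrum(omega, Fbar, "empirical", dt = attr(x, "dt") %||% NA_real_,
                  extra = extra)
}
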