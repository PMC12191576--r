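#' Parametric excitation-kernel specification
#'
#' Builds the matrix-valued excitation kernel of a multivariate Hawkes
#' process, `phi_ij(t) = alpha_ij * g_ij(t)`, where each `g_ij` is a
#' normalised waiting-time density (`integral g = 1` on `[0, Inf)`) and
#' `alpha_ij >= 0` is the branching ratio from component `j` to component
#' `i`. Supported families: `"exponential"` (parameter `beta`, the rate),
#' `"gamma"` (`shape`, `scale`), `"weibull"` (`shape`, `scale`),
#' `"lognormal"` (`meanlog`, `sdlog`) and `"powerlaw"`, a shifted Pareto
#' density `g(t) = exponent * scale^exponent / (t + scale)^(exponent + 1)`
#' with `exponent > 1` so the mean is finite.
#'
#' @param entries A data frame (or tibble) with columns `i`, `j` (1-based
#'   component indices), `family`, `alpha`, and one column per family
#'   parameter (e.g. `beta` for exponential entries; unused parameter columns
#'   may be `NA`). Alternatively a list of per-entry lists with the same
#'   fields.
#' @param d Dimension of the process. Defaults to the largest index present.
#'
#' @return An object of class `kernel_spec` with fields `d`, `family`
#'   (character matrix), `alpha` (numeric matrix), `params` (matrix of
#'   parameter lists) plus the spectral radius of the branching-ratio matrix
#'   and a stationarity flag (radius < 1).
#' @export
#' @examples
#' kernel_spec_exponential(alpha = matrix(c(.4, .3, .3, .4), 2), beta = 1)
kernel_spec <- function(entries, d = NULL) {
  if (is.data.frame(entries)) {
    entries <- lapply(seq_len(nrow(entries)), function(r) as.list(entries[r, ]))
  }
  idx <- vapply(entries, function(e) c(e$i, e$j), numeric(2))
  d <- d %||% max(idx)
  family <- matrix(NA_character_, d, d)
  alpha <- matrix(0, d, d)
  params <- matrix(vector("list", d * d), d, d)
  for (e in entries) {
    i <- e$i; j <- e$j
    fam <- match.arg(e$family, names(kernel_families))
    p <- e[setdiff(names(e), c("i", "j", "family", "alpha"))]
    p <- p[!vapply(p, function(v) is.null(v) || all(is.na(v)), logical(1))]
    kernel_families[[fam]]$validate(p)
    if (is.na(e$alpha) || e$alpha < 0) stop("alpha must be >= 0", call. = FALSE)
    family[i, j] <- fam
    alpha[i, j] <- e$alpha
    params[[i, j]] <- p
  }
  new_kernel_spec(d, family, alpha, params)
}

new_kernel_spec <- function(d, family, alpha, params) {
  rad <- spectral_radius(alpha)
  structure(
    list(d = d, family = family, alpha = alpha, params = params,
         branching_radius = rad, stationary = rad < 1),
    class = "kernel_spec"
  )
}

#' @rdname kernel_spec
#' @param alpha Branching-ratio matrix (or scalar for a univariate kernel).
#' @param beta Rate matrix of the exponential waiting-time densities
#'   (scalar recycled).
#' @export
kernel_spec_exponential <- function(alpha, beta) {
  alpha <- as.matrix(alpha)
  d <- nrow(alpha)
  beta <- matrix(beta, d, d)
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  family <- matrix("exponential", d, d)
  params <- matrix(vector("list", d * d), d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) params[[i, j]] <- list(beta = beta[i, j])
  new_kernel_spec(d, family, alpha, params)
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> d =", x$d, "\n")
  cat("families:\n"); print(x$family)
  cat("branching ratios alpha:\n"); print(x$alpha)
  cat(sprintf("spectral radius %.4f (%s)\n", x$branching_radius,
              if (x$stationary) "stationary" else "NON-stationary"))
  invisible(x)
}

# --- family registry ---------------------------------------------------------
# each family provides the normalised density g, its CDF G, the partial
# expectation P(x) = int_0^x t g(t) dt (closed form, used to integrate the CDF
# over bins exactly), mean/sd, a sampler, and parameter validation.

need <- function(p, nm) {
  for (n in nm) if (is.null(p[[n]]) || !is.finite(p[[n]]))
    stop(sprintf("missing kernel parameter '%s'", n), call. = FALSE)
}

kernel_families <- list(
  exponential = list(
    validate = function(p) { need(p, "beta"); if (p$beta <= 0) stop("beta must be > 0", call. = FALSE) },
    g = function(t, p) dexp(t, rate = p$beta),
    G = function(t, p) pexp(t, rate = p$beta),
    partial = function(x, p) (1 - exp(-p$beta * x) * (1 + p$beta * x)) / p$beta,
    mean = function(p) 1 / p$beta,
    sd = function(p) 1 / p$beta,
    r = function(n, p) rexp(n, rate = p$beta)
  ),
  gamma = list(
    validate = function(p) { need(p, c("shape", "scale")); if (p$shape <= 0 || p$scale <= 0) stop("gamma shape/scale must be > 0", call. = FALSE) },
    g = function(t, p) dgamma(t, shape = p$shape, scale = p$scale),
    G = function(t, p) pgamma(t, shape = p$shape, scale = p$scale),
    partial = function(x, p) p$shape * p$scale * pgamma(x, shape = p$shape + 1, scale = p$scale),
    mean = function(p) p$shape * p$scale,
    sd = function(p) sqrt(p$shape) * p$scale,
    r = function(n, p) rgamma(n, shape = p$shape, scale = p$scale)
  ),
  weibull = list(
    validate = function(p) { need(p, c("shape", "scale")); if (p$shape <= 0 || p$scale <= 0) stop("weibull shape/scale must be > 0", call. = FALSE) },
    g = function(t, p) dweibull(t, shape = p$shape, scale = p$scale),
    G = function(t, p) pweibull(t, shape = p$shape, scale = p$scale),
    partial = function(x, p) {
      p$scale * gamma(1 + 1 / p$shape) *
        pgamma((x / p$scale)^p$shape, shape = 1 + 1 / p$shape)
    },
    mean = function(p) p$scale * gamma(1 + 1 / p$shape),
    sd = function(p) p$scale * sqrt(gamma(1 + 2 / p$shape) - gamma(1 + 1 / p$shape)^2),
    r = function(n, p) rweibull(n, shape = p$shape, scale = p$scale)
  ),
  lognormal = list(
    validate = function(p) { need(p, c("meanlog", "sdlog")); if (p$sdlog <= 0) stop("sdlog must be > 0", call. = FALSE) },
    g = function(t, p) dlnorm(t, meanlog = p$meanlog, sdlog = p$sdlog),
    G = function(t, p) plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog),
    partial = function(x, p) {
      exp(p$meanlog + p$sdlog^2 / 2) *
        pnorm((log(pmax(x, 0)) - p$meanlog - p$sdlog^2) / p$sdlog)
    },
    mean = function(p) exp(p$meanlog + p$sdlog^2 / 2),
    sd = function(p) exp(p$meanlog + p$sdlog^2 / 2) * sqrt(expm1(p$sdlog^2)),
    r = function(n, p) rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
  ),
  powerlaw = list(
    validate = function(p) { need(p, c("exponent", "scale")); if (p$exponent <= 1 || p$scale <= 0) stop("powerlaw needs exponent > 1 and scale > 0", call. = FALSE) },
    g = function(t, p) p$exponent * p$scale^p$exponent / (t + p$scale)^(p$exponent + 1),
    G = function(t, p) 1 - (p$scale / (t + p$scale))^p$exponent,
    partial = function(x, p) {
      gam <- p$exponent; c0 <- p$scale
      gam * c0^gam * (c0^(1 - gam) - (x + c0)^(1 - gam)) / (gam - 1) -
        c0 * (1 - (c0 / (x + c0))^gam)
    },
    mean = function(p) p$scale / (p$exponent - 1),
    sd = function(p) {
      if (p$exponent <= 2) return(Inf)
      p$scale / (p$exponent - 1) * sqrt(p$exponent / (p$exponent - 2))
    },
    r = function(n, p) p$scale * ((1 - runif(n))^(-1 / p$exponent) - 1)
  )
)

entry_fam <- function(spec, i, j) {
  fam <- spec$family[i, j]
  if (is.na(fam)) NULL else kernel_families[[fam]]
}

#' Evaluate an excitation-kernel entry
#'
#' Returns `phi_ij(t) = alpha_ij g_ij(t)` for `t >= 0` and 0 for `t < 0`
#' (causality). Vectorised over `t`.
#'
#' @param spec A [kernel_spec].
#' @param i,j Target and source component indices (1-based).
#' @param t Time lag(s).
#' @export
kernel_eval <- function(spec, i, j, t) {
  stopifnot(all(is.finite(t)))
  fam <- entry_fam(spec, i, j)
  if (is.null(fam) || spec$alpha[i, j] == 0) return(numeric(length(t)) + 0 * t)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- spec$alpha[i, j] * fam$g(t[pos], spec$params[[i, j]])
  out
}

#' Cumulative excitation mass
#'
#' `int_0^t phi_ij(u) du`, the family CDF scaled by the branching ratio;
#' monotone nondecreasing with limit `alpha_ij` as `t -> Inf`.
#'
#' @inheritParams kernel_eval
#' @export
kernel_cumulative <- function(spec, i, j, t) {
  stopifnot(all(t >= 0))
  fam <- entry_fam(spec, i, j)
  if (is.null(fam) || spec$alpha[i, j] == 0) return(numeric(length(t)) + 0 * t)
  spec$alpha[i, j] * fam$G(t, spec$params[[i, j]])
}

# int_0^x G(t) dt = x G(x) - int_0^x t g(t) dt, exact per family
cdf_integral <- function(fam, p, x) {
  x * fam$G(x, p) - fam$partial(x, p)
}

#' Match a kernel family to a mean and standard deviation
#'
#' Inverts the (mean, sd) map of a waiting-time family, used to compare
#' kernel shapes on a common footing. The power-law family requires
#' `sd > mean` (coefficient of variation above 1); gamma and Weibull with
#' `sd == mean` reduce to the exponential.
#'
#' @param family One of `"gamma"`, `"powerlaw"`, `"lognormal"`, `"weibull"`,
#'   `"exponential"`.
#' @param mean,sd Target moments (time units), both positive.
#' @return Named list of family parameters.
#' @export
kernel_params_from_moments <- function(family, mean, sd) {
  stopifnot(mean > 0, sd > 0)
  cv2 <- (sd / mean)^2
  switch(family,
    exponential = {
      if (abs(sd - mean) > 1e-8 * mean)
        stop("exponential family has sd == mean", call. = FALSE)
      list(beta = 1 / mean)
    },
    gamma = list(shape = 1 / cv2, scale = mean * cv2),
    lognormal = {
      s2 <- log1p(cv2)
      list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    weibull = {
      f <- function(k) gamma(1 + 2 / k) / gamma(1 + 1 / k)^2 - 1 - cv2
      k <- uniroot(f, c(0.08, 60), tol = 1e-12)$root
      list(shape = k, scale = mean / gamma(1 + 1 / k))
    },
    powerlaw = {
      if (cv2 <= 1)
        stop("powerlaw family requires sd > mean", call. = FALSE)
      gam <- 2 * cv2 / (cv2 - 1)
      list(exponent = gam, scale = mean * (gam - 1))
    },
    stop("unknown family ", family, call. = FALSE)
  )
}

# --- coarse graining ---------------------------------------------------------

new_coarse_kernel <- function(d, dt, phi, tail_mass, alpha) {
  structure(list(d = d, dt = dt, phi = phi, tail_mass = tail_mass,
                 alpha = alpha, L = dim(phi)[3] - 1L),
            class = "coarse_kernel")
}

#' Coarse-grain an excitation kernel to a bin width
#'
#' Computes the coarse-grained kernel sequence `{Phi_k}`: with
#' `xi_k = (1/dt) * int_{k dt}^{(k+1) dt} int_0^t phi(u) du dt`, set
#' `Phi_0 = xi_0` and `Phi_k = xi_k - xi_{k-1}` for `k >= 1`. `Phi_k[i,j]`
#' is the expected excitation a component-`j` event exerts on component-`i`
#' counts `k` bins later, assuming event times uniform within a bin; `Phi_0`
#' carries the intra-bin excitation. The sequence conserves mass:
#' `sum_k Phi_k[i,j] + tail = alpha_ij`, with `Phi_0[i,j] < alpha_ij`
#' strictly for finite `dt`.
#'
#' The per-bin integrals of the family CDF are evaluated in closed form via
#' the partial-expectation identity
#' `int_0^x G = x G(x) - int_0^x t g(t) dt`; all families used here have an
#' exact partial expectation.
#'
#' @param spec A [kernel_spec].
#' @param dt Bin width, > 0.
#' @param tol Truncation tolerance: the lag cutoff `L` is the smallest lag at
#'   which every entry's remaining tail mass `alpha_ij - xi_L` is below
#'   `tol`.
#' @param max_lag Hard cap on `L`; heavy-tailed kernels may stop here, in
#'   which case the achieved tail mass is recorded (and a warning raised).
#' @return A `coarse_kernel`: `phi` is a `d x d x (L+1)` array of lag
#'   matrices, `tail_mass` the remaining mass beyond lag `L` per entry.
#' @export
#' @examples
#' ck <- coarse_grain(kernel_spec_exponential(0.4, 1), dt = 2)
#' sum(ck$phi) + ck$tail_mass  # = 0.4
coarse_grain <- function(spec, dt, tol = 1e-8, max_lag = 1e5) {
  stopifnot(dt > 0, tol > 0)
  d <- spec$d
  # entrywise xi_k on lags 0..K, extended until tails clear tol
  K <- 16L
  repeat {
    edges <- (0:(K + 1)) * dt
    xi <- array(0, c(d, d, K + 1L))
    for (i in seq_len(d)) for (j in seq_len(d)) {
      a <- spec$alpha[i, j]
      if (a == 0) next
      fam <- entry_fam(spec, i, j); p <- spec$params[[i, j]]
      Hi <- cdf_integral(fam, p, edges)
      xi[i, j, ] <- a * diff(Hi) / dt
    }
    tail_now <- spec$alpha - xi[, , K + 1L, drop = TRUE]
    if (d == 1) tail_now <- matrix(tail_now, 1, 1)
    if (max(tail_now) < tol || K >= max_lag) break
    K <- min(max_lag, K * 4L)
  }
  # trim to the smallest L with all tails below tol
  tails_by_lag <- vapply(seq_len(K + 1L), function(k) max(spec$alpha - xi[, , k]), numeric(1))
  L <- which(tails_by_lag < tol)[1]
  if (is.na(L)) {
    warning(sprintf("coarse_grain: truncation cap hit; max tail mass %.3g > tol %.3g",
                    tails_by_lag[K + 1L], tol))
    L <- K + 1L
  }
  phi <- array(0, c(d, d, L))
  phi[, , 1] <- xi[, , 1]
  if (L > 1) phi[, , 2:L] <- xi[, , 2:L] - xi[, , 1:(L - 1)]
  tail_mass <- spec$alpha - xi[, , L, drop = TRUE]
  if (d == 1) tail_mass <- matrix(tail_mass, 1, 1)
  tail_mass[tail_mass < 0] <- 0  # guard roundoff
  new_coarse_kernel(d, dt, phi, tail_mass, spec$alpha)
}

#' Closed-form coarse-grained exponential kernel (univariate entry)
#'
#' For an exponential waiting-time density with rate `beta`, the
#' coarse-grained sequence has the closed form
#' `g_0 = 1 - (1 - e^(-beta dt)) / (beta dt)` and
#' `g_k = (e^(beta dt) + e^(-beta dt) - 2) e^(-beta k dt) / (beta dt)` for
#' `k >= 1`, scaled by the branching ratio `alpha`.
#'
#' @param alpha Branching ratio (>= 0).
#' @param beta Exponential rate (> 0).
#' @param dt Bin width (> 0).
#' @param L Highest lag to return (if `NULL`, chosen so the geometric tail
#'   mass is below `tol`).
#' @param tol Tail-mass tolerance used when `L` is `NULL`.
#' @return A univariate `coarse_kernel` with lags `0..L`.
#' @export
coarse_grain_exponential_closed_form <- function(alpha, beta, dt, L = NULL,
                                                 tol = 1e-8) {
  stopifnot(beta > 0, dt > 0, alpha >= 0)
  r <- exp(-beta * dt)
  C <- (exp(beta * dt) + r - 2) / (beta * dt)
  if (is.null(L)) {
    # tail beyond lag L: alpha * C * r^(L+1) / (1 - r)
    if (alpha == 0) L <- 0L
    else L <- max(1L, ceiling(log(tol * (1 - r) / (alpha * C)) / log(r) - 1))
  }
  k <- 0:L
  g <- c(1 - (1 - r) / (beta * dt), if (L >= 1) C * r^(k[-1]))
  phi <- array(alpha * g, c(1, 1, L + 1L))
  tail_mass <- matrix(if (L >= 1) alpha * C * r^(L + 1) / (1 - r) else alpha * (1 - g[1]), 1, 1)
  new_coarse_kernel(1L, dt, phi, tail_mass, matrix(alpha, 1, 1))
}

# exponential-family fast path used inside the fitting loop: full d x d
# coarse kernel from the closed form, common lag cutoff from tol
coarse_grain_exponential_matrix <- function(alpha, beta, dt, tol = 1e-8,
                                            max_lag = 1e5) {
  d <- nrow(alpha)
  r <- exp(-beta * dt)
  C <- (exp(beta * dt) + r - 2) / (beta * dt)
  # per-entry lag needed, then common L
  Lmat <- matrix(0, d, d)
  pos <- alpha > 0
  Lmat[pos] <- ceiling(log(tol * (1 - r[pos]) / (alpha[pos] * C[pos])) / log(r[pos]) - 1)
  L <- max(1, min(max_lag, max(Lmat)))
  phi <- array(0, c(d, d, L + 1L))
  phi[, , 1] <- alpha * (1 - (1 - r) / (beta * dt))
  decay <- r
  AC <- alpha * C
  for (k in seq_len(L)) {
    phi[, , k + 1L] <- AC * decay
    decay <- decay * r
  }
  tail_mass <- AC * decay / (1 - r)
  tail_mass[!pos] <- 0
  new_coarse_kernel(d, dt, phi, tail_mass, alpha)
}

#' @export
print.coarse_kernel <- function(x, ...) {
  cat(sprintf("<coarse_kernel> d = %d, dt = %g, lags 0..%d, max tail mass %.3g\n",
              x$d, x$dt, x$L, max(x$tail_mass)))
  invisible(x)
}

#' Branching-ratio matrix of a coarse-grained kernel
#'
#' Sums the lag matrices (plus recorded tail mass) to recover the
#' branching-ratio matrix `A = sum_k Phi_k`; by mass conservation this equals
#' the integral of the continuous kernel, so `A` is independent of the bin
#' width.
#'
#' @param ck A `coarse_kernel`.
#' @return List with `A` (d x d), `radius` (spectral radius) and
#'   `stationary` (`radius < 1`).
#' @export
branching_matrix <- function(ck) {
  A <- apply(ck$phi, c(1, 2), sum) + ck$tail_mass
  rad <- spectral_radius(A)
  list(A = A, radius = rad, stationary = rad < 1)
}

#' Tidy a coarse kernel into a long tibble
#'
#' @param x A `coarse_kernel`.
#' @param ... Unused.
#' @export
tidy.coarse_kernel <- function(x, ...) {
  d <- x$d; L <- x$L
  tibble::tibble(
    lag = rep(0:L, each = d * d),
    i = rep(rep(seq_len(d), d), L + 1L),
    j = rep(rep(seq_len(d), each = d), L + 1L),
    value = as.vector(x$phi)
  )
}

# continuous-time kernel Fourier transform: Phi~(nu)[i,j] = alpha_ij *
# int_0^Inf g_ij(t) e^{-i nu t} dt; closed form for exponential/gamma,
# adaptive quadrature otherwise
kernel_fourier <- function(spec, nu) {
  d <- spec$d
  out <- array(0 + 0i, c(d, d, length(nu)))
  for (i in seq_len(d)) for (j in seq_len(d)) {
    a <- spec$alpha[i, j]
    if (a == 0) next
    p <- spec$params[[i, j]]
    fam_name <- spec$family[i, j]
    vals <- switch(fam_name,
      exponential = p$beta / (p$beta + 1i * nu),
      gamma = (1 + 1i * nu * p$scale)^(-p$shape),
      {
        fam <- kernel_families[[fam_name]]
        upper <- uniroot(function(t) fam$G(t, p) - (1 - 1e-12),
                         c(1e-8, 1e12))$root
        vapply(nu, function(v) {
          re <- integrate(function(t) fam$g(t, p) * cos(v * t), 0, upper,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
          im <- integrate(function(t) fam$g(t, p) * sin(v * t), 0, upper,
                          subdivisions = 2000L, rel.tol = 1e-10)$value
          complex(real = re, imaginary = -im)
        }, complex(1))
      }
    )
    out[i, j, ] <- a * vals
  }
  out
}
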