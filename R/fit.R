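# unconstrained-coordinate transforms per kernel family: alpha entries use
# softplus; shape parameters use the maps below
fam_shape_transforms <- list(
  exponential = list(names = "beta",
                     to = list(beta = exp), from = list(beta = log)),
  gamma = list(names = c("shape", "scale"),
               to = list(shape = exp, scale = exp),
               from = list(shape = log, scale = log)),
  weibull = list(names = c("shape", "scale"),
                 to = list(shape = exp, scale = exp),
                 from = list(shape = log, scale = log)),
  lognormal = list(names = c("meanlog", "sdlog"),
                   to = list(meanlog = identity, sdlog = exp),
                   from = list(meanlog = identity, sdlog = log)),
  powerlaw = list(names = c("exponent", "scale"),
                  to = list(exponent = function(x) 1 + exp(x), scale = exp),
                  from = list(exponent = function(x) log(x - 1), scale = log))
)

# sampled exponential kernel Phi_k = alpha beta e^{-beta k dt} dt, k >= 1
sampled_kernel_exponential_matrix <- function(alpha, beta, dt, tol = 1e-10,
                                              max_lag = 1e4) {
  d <- nrow(alpha)
  r <- exp(-pmin(beta * dt, 700))
  base <- alpha * beta * dt
  L <- 1L
  pos <- alpha > 0 & r > 0
  if (any(pos)) {
    Lv <- ceiling(log(tol * (1 - r[pos]) / pmax(base[pos] * r[pos], 1e-300)) / log(r[pos]))
    L <- max(1, min(max_lag, max(Lv, 1)))
  }
  phi <- array(0, c(d, d, L + 1L))
  decay <- r
  for (k in seq_len(L)) {
    phi[, , k + 1L] <- base * decay
    decay <- decay * r
  }
  new_coarse_kernel(d, dt, phi, matrix(0, d, d), apply(phi, c(1, 2), sum))
}

raw_layout <- function(family, d, with_mu = FALSE) {
  tr <- fam_shape_transforms[[family]]
  list(tr = tr, d = d, d2 = d * d, n_shape = length(tr$names),
       with_mu = with_mu,
       npar = (if (with_mu) d else 0) + d * d * (1 + length(tr$names)))
}

raw_to_params <- function(raw, lay) {
  d <- lay$d; d2 <- lay$d2
  off <- 0
  mu <- NULL
  if (lay$with_mu) { mu <- exp(pmin(raw[1:d], 30)); off <- d }
  alpha <- matrix(softplus(raw[(off + 1):(off + d2)]), d, d)
  off <- off + d2
  shapes <- list()
  for (nm in lay$tr$names) {
    shapes[[nm]] <- matrix(lay$tr$to[[nm]](pmin(raw[(off + 1):(off + d2)], 30)), d, d)
    off <- off + d2
  }
  list(mu = mu, alpha = alpha, shapes = shapes)
}

params_to_raw <- function(lay, alpha, shapes, mu = NULL) {
  raw <- numeric(0)
  if (lay$with_mu) raw <- log(pmax(mu, 1e-8))
  raw <- c(raw, softplus_inv(pmax(as.vector(alpha), 1e-6)))
  for (nm in lay$tr$names) raw <- c(raw, lay$tr$from[[nm]](as.vector(shapes[[nm]])))
  raw
}

spec_from_params <- function(family, alpha, shapes) {
  d <- nrow(alpha)
  fam <- matrix(family, d, d)
  params <- matrix(vector("list", d * d), d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    params[[i, j]] <- lapply(shapes, function(s) s[i, j])
  new_kernel_spec(d, fam, alpha, params)
}

coarse_kernel_from_params <- function(family, alpha, shapes, dt, tol, max_lag) {
  if (family == "exponential") {
    beta <- pmin(shapes$beta, 500 / dt)
    coarse_grain_exponential_matrix(alpha, beta, dt, tol = tol, max_lag = max_lag)
  } else {
    suppressWarnings(coarse_grain(spec_from_params(family, alpha, shapes),
                                  dt, tol = tol, max_lag = max_lag))
  }
}

# lag-1 autocorrelation heuristic for initial branching ratios
init_alpha_heuristic <- function(m) {
  d <- ncol(m)
  emp <- empirical_autocovariance(m, 1)
  R0 <- matrix(emp$R[, , 1], d, d); R1 <- matrix(emp$R[, , 2], d, d)
  a0 <- t(R1) / pmax(rep(diag(R0), each = d), 1e-8)  # a0[i,j] ~ Cov(X_n+1,i, X_n,j)/Var(X_n,j)
  a0 <- matrix(pmin(pmax(a0, 0.02), 0.7), d, d)
  rad <- spectral_radius(a0)
  if (rad >= 0.9) a0 <- a0 * 0.85 / rad
  a0
}

new_cg_fit <- function(method, family, theta, mu_hat, A_hat, lam_hat, loss,
                       converged, n_iter, seed, dt, n, d, extra = list()) {
  structure(c(list(method = method, family = family, theta = theta,
                   mu_hat = mu_hat, A_hat = A_hat, lam_hat = lam_hat,
                   loss = loss, converged = converged, n_iter = n_iter,
                   seed = seed, dt = dt, n = n, d = d), extra),
            class = "cg_fit")
}

#' Fit a Hawkes model to bin counts by the coarse-grained loss
#'
#' The estimation procedure: (1) centre the counts by the empirical mean
#' `lambda_hat`; (2) minimise the quasi-likelihood loss [cg_loss()] over the
#' kernel parameters by BFGS with finite-difference gradients in
#' unconstrained coordinates (`alpha` via softplus, positive shapes via
#' log), with a barrier keeping the branching spectral radius below
#' `1 - 1e-3`; (3) recover the baseline as
#' `mu_hat = (I - A_hat) lambda_hat / dt`. Multi-start perturbs the
#' lag-1-autocorrelation-based initial point to guard against poor local
#' minima in the kernel time scales.
#'
#' @param x A `bin_counts` object (counts plus bin width).
#' @param family Kernel family fitted to every entry (default
#'   `"exponential"`).
#' @param init Optional named list with `alpha` (d x d) and shape matrices
#'   to start from.
#' @param multistart Number of optimiser starts (>= 1).
#' @param seed Integer seed controlling the start perturbations.
#' @param tol Coarse-kernel truncation tolerance inside the loss (the lag
#'   cutoff is recomputed from it at every optimiser step).
#' @param max_lag Cap on the coarse-kernel lag cutoff inside the loss.
#' @param control Passed to [stats::optim()] (BFGS); finite-difference step
#'   defaults to `1e-5`.
#' @return A `cg_fit` with method `"cg_loss"`: kernel parameter estimates,
#'   `mu_hat`, branching matrix `A_hat`, loss and convergence diagnostics.
#'   Negative recovered baselines are clipped to zero with a warning.
#' @export
fit_cg <- function(x, family = "exponential", init = NULL, multistart = 3,
                   seed = 1, tol = 1e-8, max_lag = 1000, control = list()) {
  m <- as_count_matrix(x)
  dt <- bin_dt(x)
  n <- nrow(m); d <- ncol(m)
  if (n < 50) stop("need at least 50 bins", call. = FALSE)
  lam_hat <- colMeans(m)
  if (any(lam_hat <= 0))
    stop("a component has no events; drop it or use a longer series", call. = FALSE)
  Y <- sweep(m, 2, lam_hat)
  lay <- raw_layout(family, d)
  objective <- function(raw) {
    p <- raw_to_params(raw, lay)
    rad <- spectral_radius(p$alpha)
    if (!is.finite(rad) || rad >= 1 - 1e-3) return(1e9 * (1 + rad))
    ck <- coarse_kernel_from_params(family, p$alpha, p$shapes, dt, tol, max_lag)
    cg_loss(Y, ck, lam_hat)
  }
  default_shapes <- switch(family,
    exponential = list(beta = matrix(1 / dt, d, d)),
    gamma = list(shape = matrix(1, d, d), scale = matrix(dt, d, d)),
    weibull = list(shape = matrix(1, d, d), scale = matrix(dt, d, d)),
    lognormal = list(meanlog = matrix(log(dt), d, d), sdlog = matrix(1, d, d)),
    powerlaw = list(exponent = matrix(2.5, d, d), scale = matrix(dt, d, d)))
  if (is.null(init)) {
    init <- list(alpha = init_alpha_heuristic(m), shapes = default_shapes)
  } else if (is.null(init$shapes)) {
    init$shapes <- init[setdiff(names(init), "alpha")]
    if (!length(init$shapes)) init$shapes <- default_shapes
  }
  raw0 <- params_to_raw(lay, init$alpha, init$shapes)
  ctrl <- modifyList(list(maxit = 400, reltol = 1e-10,
                          ndeps = rep(1e-5, lay$npar)), control)
  best <- NULL
  for (s in seq_len(multistart)) {
    raw_s <- raw0
    if (s > 1) {
      set.seed(seed + 7919L * s)
      raw_s <- raw0 + rnorm(length(raw0), sd = 0.5)
    }
    opt <- tryCatch(
      optim(raw_s, objective, method = "BFGS", control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_cg_fit("cg_loss", family, NULL, rep(NA_real_, d),
                      matrix(NA_real_, d, d), lam_hat, NA_real_, FALSE, 0L,
                      seed, dt, n, d))
  }
  p <- raw_to_params(best$par, lay)
  A_hat <- p$alpha
  mu_hat <- as.numeric((diag(d) - A_hat) %*% lam_hat) / dt
  if (any(mu_hat < 0)) {
    warning("negative recovered baseline clipped to zero")
    mu_hat <- pmax(mu_hat, 0)
  }
  new_cg_fit("cg_loss", family, c(list(alpha = p$alpha), p$shapes),
             mu_hat, A_hat, lam_hat, best$value,
             best$convergence == 0, as.integer(best$counts[["function"]]),
             seed, dt, n, d)
}

#' Fit the binned-Poisson approximation by maximum likelihood
#'
#' Maximises the conditionally Poisson log-likelihood with intensities from
#' the sampled kernel `Phi(k dt) dt` (no intra-bin term) over baseline,
#' branching ratios and kernel shapes, by BFGS in unconstrained
#' coordinates. This is the naive-discretisation baseline; its estimates
#' are biased when `dt` is large relative to the kernel time scale.
#'
#' @inheritParams fit_cg
#' @return A `cg_fit` with method `"poisson_mle"` (loss is the negative
#'   log-likelihood).
#' @export
fit_binned_poisson <- function(x, family = "exponential", init = NULL,
                               multistart = 3, seed = 1, tol = 1e-10,
                               max_lag = 1000, control = list()) {
  m <- as_count_matrix(x)
  dt <- bin_dt(x)
  n <- nrow(m); d <- ncol(m)
  lam_hat <- colMeans(m)
  if (any(lam_hat <= 0))
    stop("a component has no events; drop it or use a longer series", call. = FALSE)
  lay <- raw_layout(family, d, with_mu = TRUE)
  objective <- function(raw) {
    p <- raw_to_params(raw, lay)
    rad <- spectral_radius(p$alpha)
    if (!is.finite(rad) || rad >= 1 - 1e-3) return(1e9 * (1 + rad))
    ck <- if (family == "exponential") {
      sampled_kernel_exponential_matrix(p$alpha, pmin(p$shapes$beta, 500 / dt),
                                        dt, tol, max_lag)
    } else {
      sampled_kernel(spec_from_params(family, p$alpha, p$shapes), dt, tol, max_lag)
    }
    lam <- poisson_intensities(m, p$mu, ck)
    if (any(lam <= 0)) {
      if (any(lam <= 0 & m > 0)) return(1e10)
      lam <- pmax(lam, 1e-12)
    }
    -sum(m * log(lam) - lam)
  }
  default_shapes <- list(beta = matrix(1 / dt, d, d))
  if (family != "exponential")
    stop("binned-Poisson MLE baseline implemented for the exponential family",
         call. = FALSE)
  if (is.null(init)) {
    a0 <- init_alpha_heuristic(m)
    mu0 <- pmax(as.numeric((diag(d) - a0) %*% lam_hat) / dt, 0.05)
    init <- list(mu = mu0, alpha = a0, shapes = default_shapes)
  }
  raw0 <- params_to_raw(lay, init$alpha, init$shapes, mu = init$mu)
  ctrl <- modifyList(list(maxit = 400, reltol = 1e-10,
                          ndeps = rep(1e-5, lay$npar)), control)
  best <- NULL
  for (s in seq_len(multistart)) {
    raw_s <- raw0
    if (s > 1) {
      set.seed(seed + 7919L * s)
      raw_s <- raw0 + rnorm(length(raw0), sd = 0.5)
    }
    opt <- tryCatch(optim(raw_s, objective, method = "BFGS", control = ctrl),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_cg_fit("poisson_mle", family, NULL, rep(NA_real_, d),
                      matrix(NA_real_, d, d), lam_hat, NA_real_, FALSE, 0L,
                      seed, dt, n, d))
  }
  p <- raw_to_params(best$par, lay)
  new_cg_fit("poisson_mle", family, c(list(alpha = p$alpha), p$shapes),
             p$mu, p$alpha, lam_hat, best$value,
             best$convergence == 0, as.integer(best$counts[["function"]]),
             seed, dt, n, d)
}

#' Fit by INAR(p) conditional least squares
#'
#' Regresses `X_n` on an intercept and the `p` previous count vectors,
#' yielding nonparametric estimates of `Phi(k dt) dt` (the coefficient
#' matrices, which may be negative and are passed through as such), then
#' least-squares fits the parametric family to the nonparametric sequence
#' entry by entry. The intercept over `dt` estimates the baseline.
#'
#' @param x A `bin_counts` object.
#' @param p Autoregressive order; default `ceiling(10 / dt)` clamped to
#'   `[2, 40]` (set it from the kernel mean when known, e.g.
#'   `ceiling(5 * mean_wait / dt)`).
#' @param family Parametric family fitted to the nonparametric estimates
#'   (`"exponential"`).
#' @return A `cg_fit` with method `"inar_cls"`, carrying the nonparametric
#'   coefficient matrices in `$nonparametric` (`d x d x p` array).
#' @export
fit_inar <- function(x, p = NULL, family = "exponential") {
  m <- as_count_matrix(x)
  dt <- bin_dt(x)
  n <- nrow(m); d <- ncol(m)
  p <- p %||% max(2L, min(40L, ceiling(10 / dt)))
  if (n <= p + d * p + 1)
    stop("series too short for INAR order ", p, call. = FALSE)
  X <- matrix(1, n - p, 1 + p * d)
  for (k in seq_len(p)) {
    X[, (1 + (k - 1) * d + 1):(1 + k * d)] <- m[(p - k + 1):(n - k), , drop = FALSE]
  }
  yv <- m[(p + 1):n, , drop = FALSE]
  fit <- lm.fit(X, yv)
  B <- as.matrix(fit$coefficients)
  if (anyNA(B)) stop("singular design (constant or collinear counts)", call. = FALSE)
  nonpar <- array(0, c(d, d, p))
  for (k in seq_len(p)) {
    nonpar[, , k] <- t(B[(1 + (k - 1) * d + 1):(1 + k * d), , drop = FALSE])
  }
  mu_hat <- as.numeric(B[1, ]) / dt
  if (any(mu_hat < 0)) {
    warning("negative recovered baseline clipped to zero")
    mu_hat <- pmax(mu_hat, 0)
  }
  if (family != "exponential")
    stop("parametric INAR refit implemented for the exponential family", call. = FALSE)
  alpha <- matrix(0, d, d); beta <- matrix(1 / dt, d, d)
  ks <- seq_len(p)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    h <- nonpar[i, j, ]
    # init from log-linear regression on the positive part
    posk <- which(h > 0)
    if (length(posk) >= 2) {
      lf <- lm(log(h[posk]) ~ ks[posk])
      b0 <- max(min(-coef(lf)[2] / dt, 100 / dt), 1e-3 / dt)
      a0 <- max(exp(coef(lf)[1]) / (b0 * dt), 1e-4)
    } else {
      b0 <- 1 / dt; a0 <- max(sum(h), 1e-4)
    }
    obj <- function(r) {
      a <- softplus(r[1]); b <- exp(min(r[2], 30))
      sum((h - a * b * exp(-b * ks * dt) * dt)^2)
    }
    op <- optim(c(softplus_inv(a0), log(b0)), obj, method = "Nelder-Mead",
                control = list(maxit = 500))
    alpha[i, j] <- softplus(op$par[1])
    beta[i, j] <- exp(op$par[2])
  }
  new_cg_fit("inar_cls", family, list(alpha = alpha, beta = beta),
             mu_hat, alpha, colMeans(m), NA_real_, TRUE, NA_integer_,
             NA_integer_, dt, n, d,
             extra = list(nonparametric = nonpar, order = p))
}

#' @export
print.cg_fit <- function(x, ...) {
  cat(sprintf("<cg_fit> method = %s, family = %s, n = %d bins, dt = %g\n",
              x$method, x$family, x$n, x$dt))
  cat("mu_hat:", signif(x$mu_hat, 4), "\n")
  cat("A_hat (branching ratios):\n"); print(signif(x$A_hat, 4))
  if (!is.null(x$theta$beta)) { cat("beta_hat:\n"); print(signif(x$theta$beta, 4)) }
  cat(sprintf("loss %.4f, converged %s\n", x$loss, x$converged))
  invisible(x)
}

#' Tidy a fitted Hawkes model
#'
#' One row per parameter: baselines `mu_i`, branching ratios `alpha_ij`,
#' kernel shapes (e.g. `beta_ij`).
#'
#' @param x A `cg_fit`.
#' @param ... Unused.
#' @export
tidy.cg_fit <- function(x, ...) {
  d <- x$d
  rows <- tibble::tibble(term = paste0("mu_", seq_len(d)),
                         estimate = x$mu_hat)
  grid <- expand.grid(i = seq_len(d), j = seq_len(d))
  for (nm in names(x$theta)) {
    mat <- x$theta[[nm]]
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      term = paste0(nm, "_", grid$i, grid$j),
      estimate = mat[cbind(grid$i, grid$j)]))
  }
  rows$method <- x$method
  rows
}

#' @rdname tidy.cg_fit
#' @export
glance.cg_fit <- function(x, ...) {
  tibble::tibble(method = x$method, family = x$family, loss = x$loss,
                 converged = x$converged, n_iter = x$n_iter, n = x$n,
                 d = x$d, dt = x$dt,
                 branching_radius = spectral_radius(x$A_hat))
}
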