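# canonical study configurations used across tests

# symmetric bivariate exponential model: mu = 1, alpha_s = 0.4, alpha_c = 0.3,
# beta = 1
symmetric_model <- function(alpha_s = 0.4, alpha_c = 0.3, mu = 1, beta = 1) {
  A <- matrix(c(alpha_s, alpha_c, alpha_c, alpha_s), 2)
  hawkes_model(rep(mu, 2), kernel_spec_exponential(A, beta))
}

# asymmetric bivariate exponential model with ten free parameters
asymmetric_model <- function() {
  A <- matrix(c(0.4, 0.3, 0.5, 0.2), 2)     # alpha_11=.4 alpha_12=.5 alpha_21=.3 alpha_22=.2
  B <- matrix(c(0.5, 0.3, 0.7, 1.0), 2)     # beta_ij likewise
  hawkes_model(c(1, 1), kernel_spec_exponential(A, B))
}

# brute-force double-integral coarse kernel: phi_k = (1/dt) * int over a
# source bin and a target bin k lags later of phi(t - u)
coarse_kernel_double_integral <- function(spec, i, j, k, dt,
                                          rel.tol = 1e-12) {
  inner <- function(u) {
    vapply(u, function(uu) {
      lo <- max(k * dt, uu)  # integrand vanishes for t < u (causality)
      if (lo >= (k + 1) * dt) return(0)
      integrate(function(t) kernel_eval(spec, i, j, t - uu), lo, (k + 1) * dt,
                rel.tol = rel.tol, stop.on.error = FALSE)$value
    }, numeric(1))
  }
  integrate(inner, 0, dt, rel.tol = rel.tol, stop.on.error = FALSE)$value / dt
}

# trapezoid rule on a (possibly duplicated-endpoint) grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# sequential simulation of the binned-Poisson generative model:
# X_n | past ~ Poisson(mu dt + sum_{k>=1} Phi(k dt) dt X_{n-k})
simulate_binned_poisson <- function(model, dt, n, seed) {
  set.seed(seed)
  ck <- cghawkes:::sampled_kernel(model$kernel, dt, tol = 1e-10)
  d <- model$d
  L <- ck$L
  X <- matrix(0L, n, d)
  for (k in seq_len(n)) {
    lam <- model$mu * dt
    for (l in seq_len(min(L, k - 1L))) {
      lam <- lam + matrix(ck$phi[, , l + 1L], d, d) %*% X[k - l, ]
    }
    X[k, ] <- rpois(d, lam)
  }
  bin_counts(X, dt)
}
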