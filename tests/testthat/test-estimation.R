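test_that("the quasi-likelihood loss matches hand evaluations", {
  # zero kernel: weighted sum of squares, no log-det term
  Y <- matrix(c(1, -1, 2, 0), 2)
  ck0 <- coarse_grain(kernel_spec_exponential(matrix(0, 2, 2), 1), dt = 1)
  expect_equal(cg_loss(Y, ck0, c(1, 2)), sum(Y[, 1]^2) + sum(Y[, 2]^2) / 2)
  # univariate with intra-bin mass 0.5 only: 0.5 + 4 log 2
  phi <- array(0.5, c(1, 1, 1))
  cka <- cghawkes:::new_coarse_kernel(1L, 1, phi, matrix(0, 1, 1), matrix(0.5, 1, 1))
  expect_equal(cg_loss(matrix(c(1, -1)), cka, 1), 0.5 + 4 * log(2),
               tolerance = 1e-12)
  # degenerate Phi_0 hits the barrier branch, not NaN
  phi_bad <- array(1.5, c(1, 1, 1))
  ck_bad <- cghawkes:::new_coarse_kernel(1L, 1, phi_bad, matrix(0, 1, 1),
                                         matrix(1.5, 1, 1))
  val <- cg_loss(matrix(c(1, -1)), ck_bad, 1)
  expect_true(is.finite(val) && val > 1e9)
  expect_error(cg_loss(Y, ck0, c(0, 1)), "zero")
})

test_that("loss is lower at the truth than at the null and at gross perturbations", {
  m <- asymmetric_model()
  n_better_null <- 0; n_better_pert <- 0; n_pert <- 0
  for (s in 1:6) {
    ev <- simulate_hawkes(m, 800, seed = 200 + s)
    x <- bin_events(ev, 2)
    cnt <- as.matrix(x[, c("X1", "X2")])
    lam_hat <- colMeans(cnt)
    Y <- sweep(cnt, 2, lam_hat)
    ck_true <- coarse_grain(m$kernel, 2, tol = 1e-8)
    ck_null <- coarse_grain(kernel_spec_exponential(matrix(0, 2, 2), 1), 2)
    l_true <- cg_loss(Y, ck_true, lam_hat)
    if (l_true < cg_loss(Y, ck_null, lam_hat)) n_better_null <- n_better_null + 1
    for (fac in c(0.5, 1.5)) {
      A <- m$kernel$alpha * fac
      B <- matrix(c(0.5, 0.3, 0.7, 1.0), 2) * fac
      ck_p <- coarse_grain(kernel_spec_exponential(A, B), 2, tol = 1e-8)
      n_pert <- n_pert + 1
      if (l_true < cg_loss(Y, ck_p, lam_hat)) n_better_pert <- n_better_pert + 1
    }
  }
  expect_equal(n_better_null, 6)
  expect_gte(n_better_pert / n_pert, 0.8)
})

test_that("the null model is recovered from pure Poisson counts", {
  set.seed(12)
  x <- bin_counts(matrix(rpois(1200, 3), ncol = 2), dt = 1)
  f <- fit_cg(x, multistart = 1, seed = 1)
  expect_true(f$converged)
  expect_lt(max(f$A_hat), 0.12)
  expect_lt(max(abs(f$mu_hat - 3)), 0.4)
  fp <- fit_binned_poisson(x, multistart = 1, seed = 1)
  # the binned-Poisson likelihood identifies the sampled-kernel mass and the
  # implied mean; baseline and kernel mass trade off along a flat direction
  ck_hat <- cghawkes:::sampled_kernel_exponential_matrix(
    fp$A_hat, fp$theta$beta, dt = 1)
  A_s <- branching_matrix(ck_hat)$A
  expect_lt(max(A_s), 0.25)
  lam_fit <- as.numeric(solve(diag(2) - A_s, fp$mu_hat * 1))
  expect_lt(max(abs(lam_fit - 3)), 0.25)
  fi <- fit_inar(x, p = 3)
  expect_lt(max(abs(fi$nonparametric)), 0.15)
  expect_lt(max(abs(fi$mu_hat - 3)), 0.6)
})

test_that("baseline recovery follows mu = (I - A) lambda / dt", {
  # d = 1 arithmetic: A = 0.5, lambda = 4, dt = 2 -> mu = 1
  expect_equal(as.numeric((diag(1) - 0.5) %*% 4) / 2, 1)
  # end-to-end: the fitted object reproduces the identity
  m <- asymmetric_model()
  ev <- simulate_hawkes(m, 800, seed = 41)
  x <- bin_events(ev, 2)
  f <- fit_cg(x, multistart = 1, seed = 1)
  expect_equal(f$mu_hat,
               as.numeric((diag(2) - f$A_hat) %*% f$lam_hat) / 2,
               tolerance = 1e-10)
})

test_that("binned-Poisson likelihood matches direct arithmetic and the Poisson MLE limit", {
  sp0 <- kernel_spec_exponential(matrix(0), 1)
  x1 <- bin_counts(matrix(2), dt = 1)
  expect_equal(binned_poisson_loglik(x1, mu = 1.5, sp0), 2 * log(1.5) - 1.5,
               tolerance = 1e-12)
  # without excitation the MLE of mu dt is the sample mean
  set.seed(9)
  x <- bin_counts(matrix(rpois(600, 4), ncol = 1), dt = 2)
  fp <- fit_binned_poisson(x, multistart = 1, seed = 1)
  expect_equal(fp$mu_hat * 2, mean(x$X1), tolerance = 0.1)
})

test_that("INAR conditional least squares recovers linear count dynamics", {
  # simulate the INGARCH recursion the CLS design targets
  set.seed(1234)
  n <- 6000; B <- c(0.35, 0.2); mu <- 1.5
  Xv <- numeric(n)
  for (k in 1:n) {
    lam <- mu + (if (k > 1) B[1] * Xv[k - 1] else 0) +
      (if (k > 2) B[2] * Xv[k - 2] else 0)
    Xv[k] <- rpois(1, lam)
  }
  x <- bin_counts(matrix(Xv, ncol = 1), dt = 1)
  f <- fit_inar(x, p = 2)
  expect_lt(abs(f$nonparametric[1, 1, 1] - 0.35), 0.05)
  expect_lt(abs(f$nonparametric[1, 1, 2] - 0.2), 0.05)
  expect_lt(abs(f$mu_hat - 1.5), 0.3)
  # constant series is a singular design
  expect_error(fit_inar(bin_counts(matrix(2L, 200, 1), dt = 1), p = 2),
               "singular")
})

test_that("negative nonparametric INAR coefficients are passed through", {
  m <- asymmetric_model()
  ev <- simulate_hawkes(m, 1000, seed = 77)
  x <- bin_events(ev, 2)
  f <- suppressWarnings(fit_inar(x, p = 9))
  expect_true(any(f$nonparametric < 0))   # large-bin estimates do go negative
  expect_true(all(f$theta$alpha >= 0))    # parametric refit stays in the family
})

test_that("estimators are equivariant under component relabelling", {
  m <- asymmetric_model()
  ev <- simulate_hawkes(m, 800, seed = 55)
  x <- bin_events(ev, 2)
  cnt <- as.matrix(x[, c("X1", "X2")])
  xs <- bin_counts(cnt[, c(2, 1)], dt = 2)
  f1 <- fit_cg(x, multistart = 1, seed = 1)
  f2 <- fit_cg(xs, multistart = 1, seed = 1)
  P <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(f2$A_hat, P %*% f1$A_hat %*% P, tolerance = 5e-2)
  expect_equal(f2$mu_hat, rev(f1$mu_hat), tolerance = 5e-2)
  fi1 <- suppressWarnings(fit_inar(x, p = 5))
  fi2 <- suppressWarnings(fit_inar(xs, p = 5))
  expect_equal(fi2$nonparametric[1, 1, ], fi1$nonparametric[2, 2, ],
               tolerance = 1e-8)
})

test_that("whittle loss agrees with its time-domain counterpart across parameter draws", {
  m1 <- hawkes_model(1, kernel_spec_exponential(0.5, 1))
  ev <- simulate_hawkes(m1, 2000, seed = 66)
  x <- bin_events(ev, 1)
  cnt <- as.matrix(x[, "X1", drop = FALSE])
  lam_hat <- colMeans(cnt)
  Y <- sweep(cnt, 2, lam_hat)
  set.seed(5)
  draws <- cbind(alpha = runif(10, 0.2, 0.8), beta = runif(10, 0.4, 2.5))
  l_time <- numeric(10); l_spec <- numeric(10)
  for (k in 1:10) {
    ck <- coarse_grain(kernel_spec_exponential(draws[k, 1], draws[k, 2]), 1,
                       tol = 1e-8)
    l_time[k] <- cg_loss(Y, ck, lam_hat)
    l_spec[k] <- whittle_loss(x, ck, lam = lam_hat)
  }
  expect_gt(cor(l_time, l_spec), 0.95)
})

test_that("fit results tidy into parameter tables", {
  m <- asymmetric_model()
  ev <- simulate_hawkes(m, 600, seed = 3)
  x <- bin_events(ev, 2)
  f <- fit_cg(x, multistart = 1, seed = 1)
  td <- tidy(f)
  expect_setequal(td$term, c("mu_1", "mu_2",
                             paste0("alpha_", c(11, 21, 12, 22)),
                             paste0("beta_", c(11, 21, 12, 22))))
  gl <- glance(f)
  expect_equal(gl$method, "cg_loss")
  expect_lt(gl$branching_radius, 1)
})
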