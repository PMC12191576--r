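test_that("kernel evaluation matches closed forms and causality", {
  sp <- kernel_spec_exponential(0.4, 1)
  expect_equal(kernel_eval(sp, 1, 1, 0), 0.4)
  expect_equal(kernel_eval(sp, 1, 1, -1), 0)
  sp2 <- kernel_spec_exponential(1, 2)
  expect_equal(kernel_eval(sp2, 1, 1, 0.5), 2 * exp(-1), tolerance = 1e-12)
  # causality holds for every family
  draws <- data.frame(i = 1, j = 1,
                      family = c("gamma", "weibull", "lognormal", "powerlaw"),
                      alpha = 0.5, shape = c(2, 1.5, NA, NA),
                      scale = c(0.5, 1, NA, 2), meanlog = c(NA, NA, 0, NA),
                      sdlog = c(NA, NA, 0.5, NA), exponent = c(NA, NA, NA, 2.5))
  for (r in seq_len(nrow(draws))) {
    sp_r <- kernel_spec(draws[r, ])
    expect_equal(kernel_eval(sp_r, 1, 1, c(-2, -0.1)), c(0, 0))
  }
  expect_error(kernel_spec(data.frame(i = 1, j = 1, family = "exponential",
                                      alpha = 0.3, beta = -1)))
  expect_error(kernel_spec(data.frame(i = 1, j = 1, family = "nosuch",
                                      alpha = 0.3, beta = 1)))
})

test_that("normalised densities integrate to one and cumulative mass is the CDF", {
  cases <- list(
    kernel_spec(data.frame(i = 1, j = 1, family = "gamma", alpha = 0.7,
                           shape = 2.3, scale = 0.4)),
    kernel_spec(data.frame(i = 1, j = 1, family = "weibull", alpha = 0.7,
                           shape = 1.4, scale = 1.2)),
    kernel_spec(data.frame(i = 1, j = 1, family = "lognormal", alpha = 0.7,
                           meanlog = -0.2, sdlog = 0.6)),
    kernel_spec(data.frame(i = 1, j = 1, family = "powerlaw", alpha = 0.7,
                           exponent = 3, scale = 1.5)))
  for (sp in cases) {
    total <- integrate(function(t) kernel_eval(sp, 1, 1, t), 0, Inf,
                       rel.tol = 1e-10)$value
    expect_equal(total, 0.7, tolerance = 1e-7)
    expect_equal(kernel_cumulative(sp, 1, 1, 0), 0)
    # CDF matches quadrature of the density at interior points
    for (tt in c(0.3, 1.1, 4)) {
      q <- integrate(function(u) kernel_eval(sp, 1, 1, u), 0, tt,
                     rel.tol = 1e-10)$value
      expect_equal(kernel_cumulative(sp, 1, 1, tt), q, tolerance = 1e-8)
    }
  }
  spE <- kernel_spec_exponential(1, 1)
  expect_equal(kernel_cumulative(spE, 1, 1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(kernel_cumulative(spE, 1, 1, 1e8), 1, tolerance = 1e-10)
})

test_that("moment-matching helpers invert mean and sd", {
  for (fam in c("gamma", "weibull", "lognormal")) {
    p <- kernel_params_from_moments(fam, mean = 1, sd = 1.5)
    entry <- c(list(i = 1, j = 1, family = fam, alpha = 1), p)
    sp <- kernel_spec(list(entry))
    m1 <- integrate(function(t) t * kernel_eval(sp, 1, 1, t), 0, Inf,
                    rel.tol = 1e-10)$value
    m2 <- integrate(function(t) t^2 * kernel_eval(sp, 1, 1, t), 0, Inf,
                    rel.tol = 1e-10)$value
    expect_equal(m1, 1, tolerance = 1e-6)
    expect_equal(sqrt(m2 - m1^2), 1.5, tolerance = 1e-5)
  }
  p <- kernel_params_from_moments("powerlaw", 1, 1.5)
  expect_gt(p$exponent, 2)
  expect_error(kernel_params_from_moments("powerlaw", 1, 0.8), "sd > mean")
})

test_that("coarse graining conserves mass with strict intra-bin deficit", {
  set.seed(42)
  fams <- c("exponential", "gamma", "weibull", "lognormal")
  for (rep in 1:8) {
    fam <- sample(fams, 1)
    alpha <- runif(1, 0.1, 0.9)
    p <- switch(fam,
      exponential = list(beta = runif(1, 0.3, 3)),
      gamma = list(shape = runif(1, 0.5, 4), scale = runif(1, 0.2, 2)),
      weibull = list(shape = runif(1, 0.7, 3), scale = runif(1, 0.2, 2)),
      lognormal = list(meanlog = runif(1, -1, 1), sdlog = runif(1, 0.3, 1)))
    sp <- kernel_spec(list(c(list(i = 1, j = 1, family = fam, alpha = alpha), p)))
    dt <- runif(1, 0.3, 3)
    ck <- coarse_grain(sp, dt, tol = 1e-10)
    expect_true(all(ck$phi >= 0))
    expect_true(all(ck$tail_mass >= 0))
    expect_lt(abs(sum(ck$phi) + ck$tail_mass[1, 1] - alpha), 1e-8)
    expect_lt(ck$phi[1, 1, 1], alpha)  # phi_0 < alpha for finite dt
  }
})

test_that("coarse kernel equals the double-integral definition", {
  sp <- kernel_spec(data.frame(i = 1, j = 1, family = "gamma", alpha = 0.6,
                               shape = 2, scale = 0.7))
  dt <- 1.3
  ck <- coarse_grain(sp, dt, tol = 1e-10)
  for (k in 0:3) {
    expect_equal(ck$phi[1, 1, k + 1],
                 coarse_kernel_double_integral(sp, 1, 1, k, dt),
                 tolerance = 1e-7)
  }
})

test_that("closed-form exponential coarse kernel matches quadrature and the printed form", {
  ck_quad <- coarse_grain(kernel_spec_exponential(1, 1), dt = 1, tol = 1e-12)
  ck_cf <- coarse_grain_exponential_closed_form(1, 1, 1, L = ck_quad$L)
  expect_lt(max(abs(ck_quad$phi - ck_cf$phi[, , seq_len(ck_quad$L + 1)])), 1e-10)
  expect_equal(ck_cf$phi[1, 1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(ck_cf$phi[1, 1, 2], (exp(1) + exp(-1) - 2) * exp(-1),
               tolerance = 1e-12)
  # geometric decay of the printed form
  g <- as.vector(ck_cf$phi[1, 1, ])
  expect_equal(g[2:4] / g[3:5], rep(exp(1), 3), tolerance = 1e-10)
  # zero kernel stays zero
  ck0 <- coarse_grain(kernel_spec_exponential(0, 1), dt = 1)
  expect_true(all(ck0$phi == 0))
})

test_that("intra-bin mass interpolates between 0 and alpha as dt grows", {
  sp <- kernel_spec_exponential(0.8, 1.3)
  phi0 <- vapply(c(0.01, 0.1, 1, 10, 100),
                 function(dt) coarse_grain(sp, dt, tol = 1e-10)$phi[1, 1, 1],
                 numeric(1))
  expect_true(all(diff(phi0) > 0))
  expect_lt(phi0[1], 0.01)
  expect_gt(phi0[5], 0.79)
})

test_that("branching matrix recovers continuous-time ratios independent of dt", {
  sp <- kernel_spec_exponential(matrix(c(.4, .3, .3, .4), 2), 1)
  for (dt in c(0.25, 1, 2)) {
    bm <- branching_matrix(coarse_grain(sp, dt, tol = 1e-10))
    expect_equal(bm$A, matrix(c(.4, .3, .3, .4), 2), tolerance = 1e-8)
    expect_equal(bm$radius, 0.7, tolerance = 1e-8)
  }
  bm0 <- branching_matrix(coarse_grain(kernel_spec_exponential(0, 1), 1))
  expect_equal(bm0$A, matrix(0, 1, 1))
  expect_equal(bm0$radius, 0)
})

test_that("matched-moment coarse kernels converge across families as dt grows", {
  dists <- run_kernel_shape_study(mean = 1, sd = 1.5, dts = c(0.5, 1, 2),
                                  families = c("gamma", "powerlaw",
                                               "lognormal", "weibull"))
  by_dt <- tapply(dists$distance, dists$dt, max)
  expect_true(all(diff(by_dt) < 0))
  # identical families at any dt are at distance zero
  same <- run_kernel_shape_study(mean = 1, sd = 1.5, dts = 1,
                                 families = c("gamma", "gamma"))
  if (nrow(same)) expect_equal(same$distance, rep(0, nrow(same)))
})
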