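test_that("flat spectra arise without excitation and carry the 1/2pi normalisation", {
  ck0 <- coarse_grain(kernel_spec_exponential(matrix(0, 2, 2), 1), dt = 1)
  om <- default_omega(33)
  Fcg <- spectral_density_cg(ck0, c(2, 3), om)
  expect_true(all(abs(Mod(Fcg$F[1, 1, ]) - 2 / (2 * pi)) < 1e-12))
  expect_true(all(abs(Fcg$F[1, 2, ]) < 1e-12))
  m0 <- hawkes_model(c(2, 3), kernel_spec_exponential(matrix(0, 2, 2), 1))
  Fhw <- spectral_density_binned_hawkes(m0, 1, om)
  Fpo <- spectral_density_binned_poisson(m0, 1, om)
  expect_lt(max(Mod(Fhw$F - Fcg$F)), 1e-8)
  expect_lt(max(Mod(Fpo$F - Fcg$F)), 1e-10)
  Fc <- spectral_density_hawkes(m0, seq(-4, 4, length.out = 21))
  expect_true(all(abs(Mod(Fc$F[2, 2, ]) - 3 / (2 * pi)) < 1e-12))
})

test_that("theoretical spectra are Hermitian PSD and Fourier pairs of the autocovariance", {
  m <- symmetric_model()
  ck <- coarse_grain(m$kernel, dt = 1, tol = 1e-12)
  lam <- stationary_mean(m$mu, ck)
  om <- default_omega(1501)
  Fcg <- spectral_density_cg(ck, lam, om)
  for (w in c(1, 400, 751, 1100)) {
    M <- Fcg$F[, , w]
    expect_lt(max(Mod(M - Conj(t(M)))), 1e-12)
    expect_gt(min(Re(eigen(M, only.values = TRUE)$values)), 0)
  }
  # F(-w) = conj(F(w))
  expect_lt(max(Mod(Fcg$F[, , 1] - Conj(Fcg$F[, , 1501]))), 1e-12)
  # inverse transform returns R_j
  ek <- effective_kernels(ck, tol = 1e-13)
  R <- autocovariance(ek, lam, J = 4)
  for (j in 0:3) {
    Rj <- matrix(0, 2, 2)
    for (a in 1:2) for (b in 1:2) {
      vals <- Re(Fcg$F[a, b, ] * exp(1i * om * j))
      Rj[a, b] <- trapz(om, vals)
    }
    expect_lt(max(abs(Rj - R$R[, , j + 1])), 1e-6)
  }
  # d = 1 closed form at omega = 0: lambda / (2 pi (1 - alpha)^2)
  ck1 <- coarse_grain(kernel_spec_exponential(0.4, 1), dt = 1, tol = 1e-12)
  lam1 <- stationary_mean(2, ck1)
  F0 <- spectral_density_cg(ck1, lam1, 0)
  expect_equal(Re(F0$F[1, 1, 1]), lam1 / (2 * pi * 0.6^2), tolerance = 1e-7)
})

test_that("continuous Hawkes spectrum uses the closed-form exponential transform", {
  m <- hawkes_model(1, kernel_spec_exponential(0.4, 1.5))
  nu <- c(0.3, 1, 2.7)
  Fhw <- spectral_density_hawkes(m, nu)
  lam_star <- 1 / 0.6
  for (k in seq_along(nu)) {
    phit <- 0.4 * 1.5 / (1.5 + 1i * nu[k])
    quad_re <- integrate(function(t) 0.4 * 1.5 * exp(-1.5 * t) * cos(nu[k] * t),
                         0, Inf, rel.tol = 1e-12)$value
    expect_equal(Re(phit), quad_re, tolerance = 1e-9)
    expect_equal(Re(Fhw$F[1, 1, k]), lam_star / (2 * pi * Mod(1 - phit)^2),
                 tolerance = 1e-10)
  }
})

test_that("binned spectra agree with periodograms of simulated data", {
  # binned Hawkes: simulation is the primary oracle for the aliased spectrum
  m <- symmetric_model()
  ev <- simulate_hawkes(m, 12000, seed = 17)
  x <- bin_events(ev, 1)
  per <- periodogram(x, segments = 24)
  Fth <- spectral_density_binned_hawkes(m, 1, per$omega)
  for (comp in 1:2) {
    emp <- Re(per$F[comp, comp, ])
    se <- per$se[comp, comp, ]
    th <- Re(Fth$F[comp, comp, ])
    cover <- mean(abs(emp - th) < 4 * se)
    expect_gt(cover, 0.9)
  }
  # binned Poisson: simulate its own generative recursion
  m1 <- hawkes_model(1.5, kernel_spec_exponential(0.5, 1))
  xp <- simulate_binned_poisson(m1, dt = 1, n = 12000, seed = 23)
  perp <- periodogram(xp, segments = 24)
  Fpo <- spectral_density_binned_poisson(m1, 1, perp$omega)
  emp <- Re(perp$F[1, 1, ]); se <- perp$se[1, 1, ]; th <- Re(Fpo$F[1, 1, ])
  expect_gt(mean(abs(emp - th) < 4 * se), 0.9)
})

test_that("approximation error shrinks at third order (coarse-grained) and second order (Poisson)", {
  m <- symmetric_model()
  om <- seq(0.5, pi, length.out = 40)  # away from 0, where both are exact by mass conservation
  errs <- vapply(c(0.4, 0.2, 0.1), function(dt) {
    ck <- coarse_grain(m$kernel, dt, tol = 1e-12)
    lam <- stationary_mean(m$mu, ck)
    Fc <- spectral_density_cg(ck, lam, om)
    Fh <- spectral_density_binned_hawkes(m, dt, om, tol = 1e-12)
    Fp <- spectral_density_binned_poisson(m, dt, om, tol = 1e-12)
    c(max(Mod(Fc$F - Fh$F)), max(Mod(Fp$F - Fh$F)))
  }, numeric(2))
  r_cg <- errs[1, 1:2] / errs[1, 2:3]
  r_po <- errs[2, 1:2] / errs[2, 2:3]
  expect_true(all(r_cg > 6 & r_cg < 10))
  expect_true(all(r_po > 3 & r_po < 5))
})

test_that("information loss is zero at identity, and smaller for the coarse-grained model", {
  m <- symmetric_model()
  om <- default_omega(401)
  ck <- coarse_grain(m$kernel, 1, tol = 1e-10)
  lam <- stationary_mean(m$mu, ck)
  Fcg <- spectral_density_cg(ck, lam, om)
  expect_equal(information_loss(Fcg, Fcg), 0)
  Fhw <- spectral_density_binned_hawkes(m, 1, om)
  Fpo <- spectral_density_binned_poisson(m, 1, om)
  expect_lt(abs(information_loss(Fhw, Fcg)), abs(information_loss(Fhw, Fpo)))
  expect_error(information_loss(Fhw, spectral_density_cg(ck, lam, default_omega(101))))
})

test_that("periodogram satisfies Parseval and is flat for white Poisson counts", {
  set.seed(77)
  x <- bin_counts(matrix(rpois(4000, 5), ncol = 1), dt = 1)
  per <- periodogram(x)
  # mean periodogram level ~ variance / 2pi
  expect_lt(abs(mean(Re(per$F[1, 1, ])) - var(x$X1) / (2 * pi)) /
              (var(x$X1) / (2 * pi)), 0.1)
  # constant series has no power at nonzero frequencies
  xc <- bin_counts(matrix(3L, 256, 1), dt = 1)
  perc <- periodogram(xc)
  expect_true(all(Mod(perc$F) < 1e-20))
  # averaged periodogram of Poisson noise is flat at lambda / 2pi
  per8 <- periodogram(x, segments = 8)
  expect_lt(abs(mean(Re(per8$F[1, 1, ])) - 5 / (2 * pi)) / (5 / (2 * pi)), 0.1)
})
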