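# cghawkes

Inference for multivariate Hawkes processes when only **aggregated bin
counts** are observed.

In many settings — epidemic surveillance, neural spike recordings, incident
logs — events are self-exciting but are recorded only as counts per day or
per time bin, not as time stamps. The Hawkes process models the underlying
dynamics through its conditional intensity

    lambda(t) = mu + ∫ Phi(t − u) dN(u),

with baseline rates `mu` and an excitation kernel matrix
`Phi(t) = (alpha_ij g_ij(t))`, where `alpha_ij` is the branching ratio
(expected offspring in component `i` per event in component `j`) and `g_ij`
a normalised waiting-time density. When events are binned at width `Δt`, the
exact likelihood of the count sequence is intractable, and naive
discretisation (evaluating the kernel at lag multiples of `Δt`) ignores the
excitation that happens *inside* a bin, which biases estimates as soon as
`Δt` is comparable to the kernel time scale.

`cghawkes` implements a coarse-grained count time-series model instead. The
continuous kernel is double-averaged over source and target bins,

    Phi_k = xi_k − xi_{k−1},   xi_k = (1/Δt) ∫_{kΔt}^{(k+1)Δt} ∫_0^t Phi(u) du dt,

giving bin-to-bin excitation weights `{Phi_k}` whose lag-0 term carries the
intra-bin excitation and whose total mass equals the branching matrix
exactly, at any bin width. The model is specified through conditional moment
conditions on this kernel; its second-order structure (stationary mean,
moving-average "effective" kernels, autocovariances and Bartlett spectral
density matrices) is available in closed form and approximates the true
binned Hawkes process to third order in `Δt` — one order better than the
binned-Poisson discretisation. Parameters are estimated by minimising a
quasi-likelihood loss over the AR(∞) representation, after which the
baseline is recovered as `mu = (I − A) lambda / Δt`.

The package contains:

- parametric kernel families (exponential, gamma, Weibull, log-normal,
  power-law) and the coarse-graining operator with explicit tail-mass
  accounting (`kernel_spec()`, `coarse_grain()`, `branching_matrix()`);
- exact simulators — Ogata thinning (`simulate_hawkes()`) and the cluster
  representation (`simulate_hawkes_branching()`) — plus binning
  (`bin_events()`);
- the second-order theory: `stationary_mean()`, `effective_kernels()`,
  `autocovariance()`, `conditional_moments()`, spectral densities of the
  coarse-grained / binned-Hawkes / binned-Poisson processes, periodograms
  and a spectral information-loss diagnostic;
- estimators: the coarse-grained loss fit (`fit_cg()`), binned-Poisson
  maximum likelihood (`fit_binned_poisson()`) and INAR(p) conditional least
  squares (`fit_inar()`), all returning tidy-able fit objects;
- reproducible study harnesses (`run_recovery_study()`,
  `run_information_loss_sweep()`, `run_second_order_study()`,
  `run_kernel_shape_study()`) and a small CLI (`inst/cli/cghawkes.R`).

## Worked example

Simulate a symmetric bivariate Hawkes process (baseline 1 event per unit
time in each component, self-excitation 0.4, cross-excitation 0.3,
exponential waiting times with rate 1), bin it coarsely at `Δt = 2` — twice
the kernel time scale — and recover the parameters from the counts alone:

```r
library(cghawkes)

model <- hawkes_model(
  mu = c(1, 1),
  kernel = kernel_spec_exponential(alpha = matrix(c(0.4, 0.3, 0.3, 0.4), 2),
                                   beta = 1))

events <- simulate_hawkes(model, horizon = 2000, seed = 42)
x <- bin_events(events, dt = 2)
fit <- fit_cg(x, seed = 1)
fit
#> <cg_fit> method = cg_loss, family = exponential, n = 1000 bins, dt = 2
#> mu_hat: 0.866 0.905
#> A_hat (branching ratios):
#>        [,1]   [,2]
#> [1,] 0.3916 0.3508
#> [2,] 0.3032 0.4206
#> beta_hat:
#>        [,1]   [,2]
#> [1,] 1.0520 0.9555
#> [2,] 0.8722 0.9023
#> loss 3129.3930, converged TRUE
```

The estimated branching ratios (true values 0.4 and 0.3), kernel rates
(true value 1) and baselines (true value 1) are recovered from 1000 coarse
bins despite every bin containing on average 6.7 events and most excitation
happening within a bin. `tidy(fit)` returns the ten estimates as a tibble,
`glance(fit)` the loss and convergence diagnostics.

The coarse kernel itself shows where the mass goes — at `Δt = 2` more than
half of each entry's branching ratio sits in the intra-bin term `Phi_0`,
and the lag sum reproduces the branching matrix exactly:

```r
ck <- coarse_grain(model$kernel, dt = 2)
ck
#> <coarse_kernel> d = 2, dt = 2, lags 0..9, max tail mass 2.63e-09
branching_matrix(ck)$A
#>      [,1] [,2]
#> [1,]  0.4  0.3
#> [2,]  0.3  0.4
```

`autoplot()` methods are provided for coarse kernels, spectra and recovery
studies; see the methods vignette (`vignettes/coarse-grained-hawkes.Rmd`)
for the model's assumptions, tuning parameters and numerical choices.

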