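#' Second-order comparison study
#'
#' For each bin width, computes the theoretical spectra (and
#' autocovariances) of the coarse-grained model and the binned-Poisson
#' approximation, the aliased binned-Hawkes reference spectrum, and a
#' segment-averaged empirical periodogram of one long simulated run with
#' across-segment standard errors.
#'
#' @param model A [hawkes_model].
#' @param dts Bin widths to compare.
#' @param horizon Simulation horizon for the empirical spectra.
#' @param seed Integer seed.
#' @param segments Segments for the Welch-averaged periodogram.
#' @param n_omega Frequency-grid size for the theoretical spectra.
#' @param max_lag_cov Highest autocovariance lag reported.
#' @return List of tibbles: `spectra` (long, columns `dt`, `omega`, `i`,
#'   `j`, `re`, `im`, `label`, `se`) and `autocov` (`dt`, `lag`, `i`, `j`,
#'   `value`, `label`).
#' @export
run_second_order_study <- function(model, dts = c(0.1, 1, 2), horizon = 5000,
                                   seed = 1, segments = 16, n_omega = 201,
                                   max_lag_cov = 20) {
  spec_rows <- list(); cov_rows <- list()
  ev <- simulate_hawkes(model, horizon, seed = seed)
  for (dt in dts) {
    omega <- default_omega(n_omega)
    ck <- coarse_grain(model$kernel, dt)
    lam <- stationary_mean(model$mu, ck)
    F_cg <- spectral_density_cg(ck, lam, omega)
    F_po <- spectral_density_binned_poisson(model, dt, omega)
    F_hw <- spectral_density_binned_hawkes(model, dt, omega)
    x <- bin_events(ev, dt)
    F_emp <- periodogram(x, segments = segments)
    ek <- effective_kernels(ck)
    R_cg <- autocovariance(ek, lam, max_lag_cov)
    R_emp <- empirical_autocovariance(x, max_lag_cov)
    th <- dplyr::bind_rows(tidy(F_cg), tidy(F_po), tidy(F_hw))
    th$se <- NA_real_
    emp <- tidy(F_emp)
    emp$se <- if (!is.null(F_emp$se)) as.vector(F_emp$se) else NA_real_
    sp <- dplyr::bind_rows(th, emp)
    sp$dt <- dt
    spec_rows[[length(spec_rows) + 1L]] <- sp
    cv <- dplyr::bind_rows(
      dplyr::mutate(tidy(R_cg), label = "cg"),
      dplyr::mutate(tidy(R_emp), label = "empirical"))
    cv$dt <- dt
    cov_rows[[length(cov_rows) + 1L]] <- cv
  }
  list(spectra = dplyr::bind_rows(spec_rows),
       autocov = dplyr::bind_rows(cov_rows))
}

#' Information-loss sweep over bin width and branching ratios
#'
#' For a symmetric bivariate exponential-kernel model (self-excitation
#' `alpha_s`, cross-excitation `alpha_c`), computes the spectral
#' information loss of the coarse-grained and binned-Poisson approximations
#' relative to the binned-Hawkes spectrum on a grid of bin widths.
#'
#' @param alpha_s,alpha_c Self- and cross-excitation branching ratios
#'   (vectors; combinations with `alpha_s + alpha_c < 1` are kept).
#' @param dts Bin widths.
#' @param mu Baseline intensity (scalar, both components).
#' @param beta Exponential rate of the waiting-time density.
#' @param n_omega Frequency-grid size.
#' @return Tibble with columns `dt`, `alpha_s`, `alpha_c`, `loss_cg`,
#'   `loss_po`.
#' @export
run_information_loss_sweep <- function(alpha_s = c(0.2, 0.4), alpha_c = c(0.1, 0.3),
                                       dts = c(0.25, 0.5, 1, 2), mu = 1,
                                       beta = 1, n_omega = 401) {
  grid <- expand.grid(alpha_s = alpha_s, alpha_c = alpha_c, dt = dts)
  grid <- grid[grid$alpha_s + grid$alpha_c < 1, , drop = FALSE]
  omega <- default_omega(n_omega)
  out <- purrr::pmap_dfr(grid, function(alpha_s, alpha_c, dt) {
    A <- matrix(c(alpha_s, alpha_c, alpha_c, alpha_s), 2)
    model <- hawkes_model(rep(mu, 2), kernel_spec_exponential(A, beta))
    ck <- coarse_grain(model$kernel, dt)
    lam <- stationary_mean(model$mu, ck)
    F_cg <- spectral_density_cg(ck, lam, omega)
    F_po <- spectral_density_binned_poisson(model, dt, omega)
    F_hw <- spectral_density_binned_hawkes(model, dt, omega)
    tibble::tibble(dt = dt, alpha_s = alpha_s, alpha_c = alpha_c,
                   loss_cg = information_loss(F_hw, F_cg),
                   loss_po = information_loss(F_hw, F_po))
  })
  tibble::as_tibble(out)
}

#' Parameter-recovery study
#'
#' The full simulate -> bin -> fit loop: simulates replicates of a Hawkes
#' model, bins them, fits each requested method, and summarises bias,
#' standard deviation and RMSE per parameter and method. Kernel-scale
#' estimates above `outlier_threshold` are excluded from the summary
#' metrics (the exclusion count is reported).
#'
#' @param model The generating [hawkes_model] (exponential kernels).
#' @param horizon Simulation horizon per replicate.
#' @param dt Bin width.
#' @param replicates Number of replicates.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param methods Subset of `c("cg", "poisson", "inar")`.
#' @param multistart Optimiser starts per fit.
#' @param inar_order INAR order; default `ceiling(5 * max kernel mean / dt)`.
#' @param outlier_threshold Exclusion threshold for shape-parameter
#'   estimates.
#' @return A `recovery_study`: list with `results` (one row per replicate x
#'   method x parameter), `summary` (bias/sd/rmse per parameter x method),
#'   `truth`, and the configuration.
#' @export
run_recovery_study <- function(model, horizon = 1000, dt = 2, replicates = 50,
                               seed = 1, methods = c("cg", "poisson", "inar"),
                               multistart = 3, inar_order = NULL,
                               outlier_threshold = 100) {
  stopifnot(replicates >= 1)
  d <- model$d
  truth <- true_params_tibble(model)
  inar_order <- inar_order %||% {
    mw <- max(vapply(seq_len(d * d), function(k) {
      i <- (k - 1) %% d + 1; j <- (k - 1) %/% d + 1
      if (model$kernel$alpha[i, j] == 0) return(0)
      entry_fam(model$kernel, i, j)$mean(model$kernel$params[[i, j]])
    }, numeric(1)))
    max(2L, ceiling(5 * mw / dt))
  }
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rs <- seed + r
    ev <- simulate_hawkes(model, horizon, seed = rs)
    x <- bin_events(ev, dt)
    fits <- list()
    if ("cg" %in% methods)
      fits$cg <- fit_cg(x, multistart = multistart, seed = rs)
    if ("poisson" %in% methods)
      fits$poisson <- suppressWarnings(
        fit_binned_poisson(x, multistart = multistart, seed = rs))
    if ("inar" %in% methods)
      fits$inar <- suppressWarnings(fit_inar(x, p = inar_order))
    tr <- purrr::map_dfr(fits, function(f) {
      td <- suppressWarnings(tidy(f))
      td$converged <- f$converged
      td
    })
    tr$replicate <- r
    tr$seed <- rs
    rows[[r]] <- tr
  }
  results <- dplyr::bind_rows(rows)
  summary <- summarise_recovery(results, truth, outlier_threshold)
  structure(list(results = results, summary = summary, truth = truth,
                 horizon = horizon, dt = dt, replicates = replicates,
                 seed = seed, inar_order = inar_order,
                 outlier_threshold = outlier_threshold),
            class = "recovery_study")
}

true_params_tibble <- function(model) {
  d <- model$d
  grid <- expand.grid(i = seq_len(d), j = seq_len(d))
  shape_rows <- NULL
  if (all(model$kernel$family %in% "exponential")) {
    beta <- matrix(0, d, d)
    for (i in seq_len(d)) for (j in seq_len(d))
      beta[i, j] <- model$kernel$params[[i, j]]$beta
    shape_rows <- tibble::tibble(term = paste0("beta_", grid$i, grid$j),
                                 truth = beta[cbind(grid$i, grid$j)])
  }
  dplyr::bind_rows(
    tibble::tibble(term = paste0("mu_", seq_len(d)), truth = model$mu),
    tibble::tibble(term = paste0("alpha_", grid$i, grid$j),
                   truth = model$kernel$alpha[cbind(grid$i, grid$j)]),
    shape_rows)
}

summarise_recovery <- function(results, truth, outlier_threshold) {
  joined <- dplyr::inner_join(results, truth, by = "term")
  joined$excluded <- grepl("^beta", joined$term) &
    abs(joined$estimate) > outlier_threshold
  joined |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$method, .data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      n_used = dplyr::n(),
      median = median(.data$estimate),
      bias = mean(.data$estimate) - .data$truth[1],
      sd = sd(.data$estimate),
      rmse = sqrt(mean((.data$estimate - .data$truth[1])^2)),
      .groups = "drop") |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(.data$method, .data$term) |>
        dplyr::summarise(n_excluded = sum(.data$excluded), .groups = "drop"),
      by = c("method", "term"))
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("<recovery_study> %d replicates, T = %g, dt = %g\n",
              x$replicates, x$horizon, x$dt))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @rdname run_recovery_study
#' @param x A `recovery_study`.
#' @param ... Unused.
#' @export
tidy.recovery_study <- function(x, ...) x$results

#' @rdname run_recovery_study
#' @export
glance.recovery_study <- function(x, ...) {
  tibble::tibble(replicates = x$replicates, horizon = x$horizon, dt = x$dt,
                 seed = x$seed, inar_order = x$inar_order)
}

#' Kernel-shape robustness study
#'
#' Coarse-grains gamma, power-law, log-normal and Weibull waiting-time
#' densities matched on a common mean and standard deviation, and reports
#' pairwise sup-norm distances between the coarse kernels at each bin
#' width: the distances shrink as the bin width grows and the kernel shape
#' is averaged out.
#'
#' @param mean,sd Common moments of the matched densities (power-law
#'   requires `sd > mean` and is dropped otherwise).
#' @param dts Bin widths.
#' @param families Families to compare.
#' @param alpha Branching ratio applied to every density.
#' @return Tibble with columns `dt`, `family_a`, `family_b`, `distance`.
#' @export
run_kernel_shape_study <- function(mean = 1, sd = 1.5, dts = c(0.5, 1, 2),
                                   families = c("gamma", "powerlaw",
                                                "lognormal", "weibull"),
                                   alpha = 0.5) {
  keep <- vapply(families, function(f) {
    !(f == "powerlaw" && sd <= mean) && !(f == "exponential" && sd != mean)
  }, logical(1))
  families <- families[keep]
  specs <- lapply(families, function(f) {
    p <- kernel_params_from_moments(f, mean, sd)
    kernel_spec(c(list(c(list(i = 1, j = 1, family = f, alpha = alpha), p))))
  })
  names(specs) <- families
  out <- list()
  for (dt in dts) {
    cks <- lapply(specs, coarse_grain, dt = dt, tol = 1e-6, max_lag = 5e4)
    Lmax <- max(vapply(cks, function(ck) ck$L, numeric(1)))
    seqs <- lapply(cks, function(ck) {
      v <- as.vector(ck$phi[1, 1, ])
      c(v, rep(0, Lmax + 1 - length(v)))
    })
    for (a in seq_along(families)) for (b in seq_along(families)) {
      if (a >= b) next
      out[[length(out) + 1L]] <- tibble::tibble(
        dt = dt, family_a = families[a], family_b = families[b],
        distance = max(abs(seqs[[a]] - seqs[[b]])))
    }
  }
  dplyr::bind_rows(out)
}
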