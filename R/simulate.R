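#' Multivariate Hawkes model
#'
#' A Hawkes process with conditional intensity
#' `lambda(t) = mu + int_0^t Phi(t - u) dN(u)`: baseline rates `mu` plus
#' kernel-weighted contributions of past events. Stationary iff the spectral
#' radius of the branching matrix `A = int Phi` is below one.
#'
#' @param mu Baseline intensity vector (events per unit time, >= 0).
#' @param kernel A [kernel_spec] of matching dimension.
#' @return An object of class `hawkes_model`.
#' @export
#' @examples
#' m <- hawkes_model(mu = c(1, 1),
#'                   kernel = kernel_spec_exponential(
#'                     alpha = matrix(c(.4, .3, .3, .4), 2), beta = 1))
hawkes_model <- function(mu, kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  mu <- as.numeric(mu)
  if (length(mu) == 1) mu <- rep(mu, kernel$d)
  stopifnot(length(mu) == kernel$d, all(mu >= 0))
  structure(list(mu = mu, kernel = kernel, d = kernel$d,
                 stationary = kernel$stationary),
            class = "hawkes_model")
}

#' @export
print.hawkes_model <- function(x, ...) {
  cat("<hawkes_model> d =", x$d, " mu =", x$mu, "\n")
  print(x$kernel)
  invisible(x)
}

#' Stationary intensity of a Hawkes model
#'
#' Solves `(I - A) lambda* = mu` for the long-run event rate per component,
#' where `A` is the continuous-time branching matrix.
#'
#' @param model A [hawkes_model].
#' @return Numeric vector of stationary rates (events per unit time).
#' @export
stationary_intensity <- function(model) {
  A <- model$kernel$alpha
  rad <- spectral_radius(A)
  if (rad >= 1)
    stop(sprintf("model is not stationary: branching spectral radius %.3f >= 1", rad),
         call. = FALSE)
  as.numeric(solve(diag(model$d) - A, model$mu))
}

new_hawkes_events <- function(time, component, horizon, d) {
  ord <- order(time)
  out <- tibble::tibble(time = time[ord], component = as.integer(component[ord]))
  attr(out, "horizon") <- horizon
  attr(out, "d") <- d
  class(out) <- c("hawkes_events", class(out))
  out
}

default_burn_in <- function(model, multiplier = 20) {
  d <- model$d
  means <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (model$kernel$alpha[i, j] > 0) {
      fam <- entry_fam(model$kernel, i, j)
      means <- max(means, fam$mean(model$kernel$params[[i, j]]))
    }
  }
  multiplier * means
}

#' Simulate a Hawkes process by Ogata thinning
#'
#' Exact sampling of event times on `(0, T]` by rejection from a dominating
#' rate. Exponential kernel matrices use O(1) Markovian intensity updates
#' (the total intensity decays between events, so the post-event intensity
#' dominates); other families use history sums with a locally constant
#' dominating rate refreshed on a fixed step, and require bounded
#' waiting-time densities (gamma/Weibull shape >= 1). A burn-in window
#' before time 0 (default 20x the longest kernel mean) approximates the
#' stationary regime; burn-in events are discarded but excite the retained
#' window.
#'
#' @param model A [hawkes_model].
#' @param horizon Observation horizon `T` (> 0).
#' @param seed Integer seed (required; same seed gives identical output).
#' @param burn_in Burn-in length before time 0; default chosen from the
#'   kernel means.
#' @param max_events Explosion guard: abort past this many accepted events.
#' @return A `hawkes_events` tibble with columns `time`, `component` and
#'   attributes `horizon`, `d`.
#' @export
simulate_hawkes <- function(model, horizon, seed, burn_in = NULL,
                            max_events = 5e6) {
  stopifnot(horizon > 0)
  if (missing(seed)) stop("simulate_hawkes requires an explicit seed", call. = FALSE)
  set.seed(seed)
  if (!model$stationary)
    warning("branching spectral radius >= 1; simulating on a finite horizon only")
  burn_in <- burn_in %||% default_burn_in(model)
  if (all(model$kernel$family %in% c("exponential", NA_character_))) {
    sim_thinning_exponential(model, horizon, burn_in, max_events)
  } else {
    sim_thinning_general(model, horizon, burn_in, max_events)
  }
}

sim_thinning_exponential <- function(model, horizon, burn_in, max_events) {
  d <- model$d
  alpha <- model$kernel$alpha
  beta <- matrix(1, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    if (alpha[i, j] > 0) beta[i, j] <- model$kernel$params[[i, j]]$beta
  jump <- alpha * beta
  mu <- model$mu
  S <- matrix(0, d, d)      # S[i,j]: decayed excitation of component i from past j-events
  t <- -burn_in
  n_acc <- 0L
  cap <- 4096L; buf_t <- numeric(cap); buf_c <- integer(cap); nb <- 0L
  # the total intensity decays between events for exponential kernels, so the
  # value just after the previous candidate dominates on the next interval
  repeat {
    Lam <- sum(mu) + sum(S)
    w <- rexp(1L, Lam)
    tn <- t + w
    if (tn > horizon) break
    S <- S * exp(-beta * w)
    t <- tn
    lam <- mu + rowSums(S)
    D <- sum(lam)
    if (runif(1L) * Lam <= D) {
      comp <- sample.int(d, 1L, prob = lam)
      S[, comp] <- S[, comp] + jump[, comp]
      if (t > 0) {
        nb <- nb + 1L
        if (nb > cap) { cap <- cap * 2L; buf_t <- c(buf_t, numeric(cap / 2)); buf_c <- c(buf_c, integer(cap / 2)) }
        buf_t[nb] <- t; buf_c[nb] <- comp
      }
      n_acc <- n_acc + 1L
      if (n_acc > max_events)
        stop("explosion guard: more than ", max_events, " events", call. = FALSE)
    }
  }
  new_hawkes_events(buf_t[seq_len(nb)], buf_c[seq_len(nb)], horizon, d)
}

# bound of g over [a, a + h] for a unimodal density with mode m
g_window_max <- function(fam, p, a, h, m) {
  hi <- pmax(fam$g(a, p), fam$g(a + h, p))
  inwin <- a <= m & m <= a + h
  if (any(inwin)) hi[inwin] <- pmax(hi[inwin], fam$g(m, p))
  hi
}

family_mode <- function(fam_name, p) {
  switch(fam_name,
    exponential = 0,
    gamma = if (p$shape >= 1) (p$shape - 1) * p$scale else
      stop("thinning requires gamma shape >= 1 (unbounded density)", call. = FALSE),
    weibull = if (p$shape >= 1) p$scale * ((p$shape - 1) / p$shape)^(1 / p$shape) else
      stop("thinning requires weibull shape >= 1 (unbounded density)", call. = FALSE),
    lognormal = exp(p$meanlog - p$sdlog^2),
    powerlaw = 0
  )
}

sim_thinning_general <- function(model, horizon, burn_in, max_events) {
  d <- model$d
  spec <- model$kernel
  mu <- model$mu
  # per-entry truncation window (tail mass < 1e-8) and mode
  W <- matrix(0, d, d); modes <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (spec$alpha[i, j] == 0) next
    fam <- entry_fam(spec, i, j); p <- spec$params[[i, j]]
    W[i, j] <- uniroot(function(t) fam$G(t, p) - (1 - 1e-8), c(1e-10, 1e12))$root
    modes[i, j] <- family_mode(spec$family[i, j], p)
  }
  mean_wait <- min(vapply(seq_len(d * d), function(k) {
    i <- (k - 1) %% d + 1; j <- (k - 1) %/% d + 1
    if (spec$alpha[i, j] == 0) return(Inf)
    entry_fam(spec, i, j)$mean(spec$params[[i, j]])
  }, numeric(1)))
  ddom <- if (is.finite(mean_wait)) mean_wait / 10 else horizon / 100
  hist_t <- vector("list", d)
  for (j in seq_len(d)) hist_t[[j]] <- numeric(0)
  intensity_at <- function(t) {
    lam <- mu
    for (j in seq_len(d)) {
      hs <- hist_t[[j]]
      if (!length(hs)) next
      ages <- t - hs
      for (i in seq_len(d)) {
        a <- spec$alpha[i, j]
        if (a == 0) next
        keep <- ages >= 0 & ages <= W[i, j]
        if (any(keep))
          lam[i] <- lam[i] + a * sum(entry_fam(spec, i, j)$g(ages[keep], spec$params[[i, j]]))
      }
    }
    lam
  }
  bound_over <- function(t, h) {
    b <- sum(mu)
    for (j in seq_len(d)) {
      hs <- hist_t[[j]]
      if (!length(hs)) next
      ages <- t - hs
      for (i in seq_len(d)) {
        a <- spec$alpha[i, j]
        if (a == 0) next
        keep <- ages >= 0 & ages <= W[i, j]
        if (any(keep)) {
          fam <- entry_fam(spec, i, j); p <- spec$params[[i, j]]
          b <- b + a * sum(g_window_max(fam, p, ages[keep], h, modes[i, j]))
        }
      }
    }
    b
  }
  t <- -burn_in
  times <- numeric(0); comps <- integer(0)
  n_acc <- 0L
  refresh_at <- t
  B <- bound_over(t, ddom)
  repeat {
    if (t >= refresh_at) { B <- bound_over(t, ddom); refresh_at <- t + ddom }
    w <- rexp(1L, B)
    if (t + w > refresh_at) { t <- refresh_at; next }
    t <- t + w
    if (t > horizon) break
    lam <- intensity_at(t)
    D <- sum(lam)
    if (runif(1L) * B <= D) {
      comp <- sample.int(d, 1L, prob = lam)
      hist_t[[comp]] <- c(hist_t[[comp]], t)
      if (t > 0) { times <- c(times, t); comps <- c(comps, comp) }
      n_acc <- n_acc + 1L
      if (n_acc > max_events)
        stop("explosion guard: more than ", max_events, " events", call. = FALSE)
      B <- bound_over(t, ddom); refresh_at <- t + ddom
      # prune history beyond every window
      maxW <- max(W)
      for (j in seq_len(d)) hist_t[[j]] <- hist_t[[j]][t - hist_t[[j]] <= maxW]
    }
  }
  new_hawkes_events(times, comps, horizon, d)
}

#' Simulate a Hawkes process by the cluster (branching) representation
#'
#' Immigrant events arrive as Poisson processes with rates `mu`; each event
#' of component `j` independently spawns `Poisson(alpha_ij)` offspring in
#' component `i` at lags drawn from the waiting-time density `g_ij`. This is
#' an exact sampler for any kernel family and serves as an independent
#' cross-check of the thinning sampler. Burn-in as in [simulate_hawkes].
#'
#' @inheritParams simulate_hawkes
#' @return A `hawkes_events` tibble.
#' @export
simulate_hawkes_branching <- function(model, horizon, seed, burn_in = NULL,
                                      max_events = 5e6) {
  stopifnot(horizon > 0)
  if (missing(seed)) stop("simulate_hawkes_branching requires an explicit seed", call. = FALSE)
  set.seed(seed)
  burn_in <- burn_in %||% default_burn_in(model)
  d <- model$d
  spec <- model$kernel
  t0 <- -burn_in
  times <- numeric(0); comps <- integer(0)
  # immigrants
  gen_t <- numeric(0); gen_c <- integer(0)
  for (i in seq_len(d)) {
    n_imm <- rpois(1L, model$mu[i] * (horizon - t0))
    if (n_imm > 0) {
      gen_t <- c(gen_t, runif(n_imm, t0, horizon))
      gen_c <- c(gen_c, rep(i, n_imm))
    }
  }
  total <- 0L
  while (length(gen_t)) {
    times <- c(times, gen_t); comps <- c(comps, gen_c)
    total <- total + length(gen_t)
    if (total > max_events)
      stop("explosion guard: more than ", max_events, " events", call. = FALSE)
    new_t <- numeric(0); new_c <- integer(0)
    for (j in seq_len(d)) {
      parents <- gen_t[gen_c == j]
      if (!length(parents)) next
      for (i in seq_len(d)) {
        a <- spec$alpha[i, j]
        if (a == 0) next
        n_off <- rpois(length(parents), a)
        tot <- sum(n_off)
        if (tot == 0) next
        fam <- entry_fam(spec, i, j)
        lags <- fam$r(tot, spec$params[[i, j]])
        off <- rep(parents, n_off) + lags
        off <- off[off <= horizon]
        if (length(off)) { new_t <- c(new_t, off); new_c <- c(new_c, rep(i, length(off))) }
      }
    }
    gen_t <- new_t; gen_c <- new_c
  }
  keep <- times > 0
  new_hawkes_events(times[keep], comps[keep], horizon, d)
}

#' Bin an event stream into counts
#'
#' Counts events in half-open bins `((n-1) dt, n dt]` for
#' `n = 1, ..., floor(T / dt)`; an event exactly on a bin edge belongs to the
#' left (earlier-indexed) bin and a trailing partial bin is discarded.
#'
#' @param events A `hawkes_events` tibble (from the simulators) or any data
#'   frame with `time` and `component` columns plus a known horizon.
#' @param dt Bin width (> 0).
#' @param horizon Horizon `T`; taken from the events attribute if present.
#' @return A `bin_counts` tibble: column `bin` plus one integer count column
#'   per component (`X1`, ..., `Xd`), with attributes `dt` and `horizon`.
#' @export
bin_events <- function(events, dt, horizon = attr(events, "horizon")) {
  stopifnot(dt > 0, !is.null(horizon))
  d <- attr(events, "d") %||% max(events$component)
  n <- floor(horizon / dt + 1e-9)
  bins <- ceiling(events$time / dt - 1e-12)
  bins[bins < 1L] <- 1L
  counts <- matrix(0L, n, d)
  for (j in seq_len(d)) {
    b <- bins[events$component == j & bins <= n]
    if (length(b)) counts[, j] <- tabulate(b, nbins = n)
  }
  bin_counts(counts, dt)
}

#' Construct a bin-count series
#'
#' Wraps an `n x d` nonnegative integer matrix (or data frame of counts) as
#' a `bin_counts` tibble with its bin width, the container consumed by the
#' spectral and fitting functions.
#'
#' @param counts Matrix or data frame of nonnegative integer counts, one row
#'   per bin, one column per component.
#' @param dt Bin width in time units.
#' @export
bin_counts <- function(counts, dt) {
  m <- as_count_matrix(counts)
  stopifnot(dt > 0, all(m >= 0), all(m == round(m)))
  d <- ncol(m)
  out <- tibble::as_tibble(as.data.frame(m, col.names = paste0("X", seq_len(d))),
                           .name_repair = "minimal")
  names(out) <- paste0("X", seq_len(d))
  out <- dplyr::mutate(out, bin = dplyr::row_number(), .before = 1)
  attr(out, "dt") <- dt
  attr(out, "convention") <- "right-closed"
  class(out) <- c("bin_counts", class(out))
  out
}

bin_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) stop("bin width `dt` not recorded on this object", call. = FALSE)
  dt
}
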