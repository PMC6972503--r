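# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: plain R loops, deSolve, and direct
# textbook formulas.

# Fine-timestep forward-Euler integration of the single-cell model, written
# as an explicit R loop.  Returns spike times.
euler_fine_oracle <- function(p, I_app, T, dt = 5e-4, V0 = p$v_r, u0 = 0) {
  nsteps <- round(T / dt)
  V <- V0
  u <- u0
  spikes <- numeric(0)
  for (step in seq_len(nsteps)) {
    k <- if (V <= p$v_t) p$k_low else p$k_high
    Vn <- V + dt * (k * (V - p$v_r) * (V - p$v_t) - u + I_app) / p$C_m
    un <- u + dt * p$a * (p$b * (V - p$v_r) - u)
    if (Vn >= p$v_peak) {
      Vn <- p$c
      un <- un + p$d
      spikes <- c(spikes, step * dt)
    }
    V <- Vn
    u <- un
  }
  spikes
}

# Numerical integration of the gating ODE s' = alpha*[T]*(1 - s) - beta*s
# with [T] = 1, via deSolve (adaptive high-accuracy solver).
gate_rise_ode_oracle <- function(s0, alpha, beta, t_end) {
  f <- function(t, y, parms) list(alpha * (1 - y) - beta * y)
  out <- deSolve::ode(y = s0, times = c(0, t_end), func = f, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), 2])
}

# Direct evaluation of the synchrony measure from its definition: per-neuron
# Gaussian sums evaluated point by point with outer(), population average,
# and time-averaged variances.
synchrony_brute_oracle <- function(raster, N, window, kernel_sd = 2,
                                   grid_step = 0.5) {
  grid <- seq(window$t_start, window$t_end, by = grid_step)
  sp <- raster[raster$time > window$t_start & raster$time <= window$t_end, ]
  traces <- matrix(0, length(grid), N)
  for (i in seq_len(N)) {
    ts <- sp$time[sp$neuron == i]
    if (length(ts) == 0) next
    d <- outer(grid, ts, "-")
    v <- dnorm(d, sd = kernel_sd)
    v[abs(d) > 5 * kernel_sd] <- 0
    traces[, i] <- rowSums(v)
  }
  vbar <- rowMeans(traces)
  num <- mean(vbar^2) - mean(vbar)^2
  sig <- colMeans(traces^2) - colMeans(traces)^2
  num / mean(sig[sig > 0])
}

# One-line filter-then-sum evaluation of the bistability score.
bistability_brute_oracle <- function(diffs, threshold = 0.3) {
  d <- diffs[!is.na(diffs)]
  sum(d[d > threshold])
}

# Exhaustive application of the transition-slope rule.
slope_scan_oracle <- function(I, S, smax) {
  for (k in seq_along(S)) {
    if (!is.na(S[k]) && S[k] > smax / 2) {
      if (k == 1) return(NA_real_)
      return((S[k] - S[k - 1]) / (I[k] - I[k - 1]))
    }
  }
  NA_real_
}

derive_seeds_for_test <- ingsim:::derive_seeds

# Deterministic seeds for small helper networks.
test_config <- function(N, p_conn, g_syn, I_mu, sigma_I = 6, tag = 1) {
  network_config(N = N, p_conn = p_conn, g_syn = g_syn, I_mu = I_mu,
                 sigma_I = sigma_I, seed_topology = 100 * tag + 1,
                 seed_drive = 100 * tag + 2, seed_init = 100 * tag + 3)
}
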