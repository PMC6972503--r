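#' Measurement window
#'
#' Half-open interval (`t_start`, `t_end`] over which spikes are analysed.
#' The standard protocol uses (500, 1000) for dynamics established from
#' random initial conditions and (1500, 2000) for dynamics following the
#' perturbation.
#'
#' @param t_start,t_end window bounds (ms), `t_end > t_start`.
#' @return Object of class `measure_window`.
#' @export
measure_window <- function(t_start, t_end) {
  stop_if_not_finite(c(t_start, t_end), "measure_window")
  if (t_end <= t_start) stop("t_end must exceed t_start", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end), class = "measure_window")
}

#' @rdname measure_window
#' @details `window_before()` and `window_after()` return the standard
#'   random-initial-conditions window (500, 1000) and post-perturbation
#'   window (1500, 2000).
#' @export
window_before <- function() measure_window(500, 1000)

#' @rdname measure_window
#' @export
window_after <- function() measure_window(1500, 2000)

raster_df <- function(raster) {
  if (inherits(raster, "sim_result")) raster <- raster$raster
  stopifnot(is.data.frame(raster), all(c("neuron", "time") %in% names(raster)))
  raster
}

raster_N <- function(raster, N) {
  if (!is.null(N)) return(as.integer(N))
  if (inherits(raster, "sim_result")) return(raster$config$N)
  if (!is.null(attr(raster, "N"))) return(as.integer(attr(raster, "N")))
  stop("N (number of neurons) must be supplied when the raster does not ",
       "carry it", call. = FALSE)
}

# Gaussian-convolved spike-density traces on a uniform grid over the window.
# Kernel truncated at +/- 5 SD; returns an n_grid x N matrix.  Each spike
# only touches the grid points inside its kernel support, accumulated in
# one vectorized pass.
convolve_traces <- function(sp, N, window, kernel_sd, grid_step) {
  grid <- seq(window$t_start, window$t_end, by = grid_step)
  ng <- length(grid)
  traces <- matrix(0, nrow = ng, ncol = N)
  if (nrow(sp) == 0) return(traces)
  half_w <- 5 * kernel_sd
  nk <- floor(2 * half_w / grid_step) + 2L
  ts <- sp$time
  j0 <- ceiling((ts - half_w - window$t_start) / grid_step - 1e-9) + 1
  J <- outer(j0, seq_len(nk) - 1L, "+")
  Tg <- window$t_start + (J - 1) * grid_step
  D <- Tg - ts  # ts recycles down columns (rows index spikes)
  Vv <- dnorm(D, sd = kernel_sd)
  keep <- J >= 1 & J <= ng & abs(D) <= half_w + 1e-12
  L <- (rep(sp$neuron, times = nk) - 1) * ng + J
  agg <- rowsum(Vv[keep], L[keep])
  traces[as.integer(rownames(agg))] <- agg
  traces
}

#' Synchrony measure on a spike raster
#'
#' Golomb-Rinzel-style coincidence measure.  Each neuron's spike train is
#' convolved with a Gaussian kernel to give a smoothed trace
#' \eqn{V_i(t)}; with \eqn{V(t)} the population average over all N cells,
#' the measure is
#' \deqn{S = \frac{\langle V^2\rangle - \langle V\rangle^2}
#'            {\frac{1}{N}\sum_i (\langle V_i^2\rangle -
#'             \langle V_i\rangle^2)}}
#' with time averages taken over the window.  S = 0 indicates completely
#' asynchronous firing and S = 1 a fully synchronous population (up to
#' discretization).  Neurons with zero trace variance in the window
#' (typically silent cells) are excluded from the denominator mean; their
#' count is reported in the `excluded` attribute.  If the window is silent
#' or every individual variance is zero the measure is undefined and `NA`
#' is returned with a `reason` attribute (never a silent 0).
#'
#' @param raster a spike raster `data.frame` (`neuron`, `time`) or a
#'   `sim_result`.
#' @param window a [measure_window()].
#' @param kernel_sd Gaussian kernel standard deviation (ms).
#' @param grid_step evaluation grid step (ms).
#' @param N number of neurons in the population (taken from the raster's
#'   metadata when available).
#'
#' @return Numeric scalar S with attributes `excluded` (number of
#'   zero-variance neurons left out of the denominator) and, when
#'   undefined, `reason`.
#' @export
synchrony_measure <- function(raster, window = window_before(),
                              kernel_sd = 2, grid_step = 0.5, N = NULL) {
  N <- raster_N(raster, N)
  df <- raster_df(raster)
  stopifnot(inherits(window, "measure_window"), kernel_sd > 0, grid_step > 0)
  sp <- df[df$time > window$t_start & df$time <= window$t_end, , drop = FALSE]
  if (nrow(sp) == 0) {
    return(structure(NA_real_, excluded = N, reason = "all-silent window"))
  }
  traces <- convolve_traces(sp, N, window, kernel_sd, grid_step)
  vbar <- rowMeans(traces)
  num <- mean(vbar^2) - mean(vbar)^2
  sig_i <- colMeans(traces^2) - colMeans(traces)^2
  included <- sig_i > 0
  if (!any(included)) {
    return(structure(NA_real_, excluded = N,
                     reason = "all individual variances zero"))
  }
  structure(num / mean(sig_i[included]), excluded = sum(!included))
}

#' Synchrony before and after the perturbation
#'
#' Computes the synchrony measure over the random-initial-conditions window
#' and the post-perturbation window of one simulation and their difference.
#' A difference well above zero flags a perturbation-induced transition
#' from asynchrony to synchrony (bistability).
#'
#' @param result a `sim_result` (or raw raster with `N` supplied).
#' @param window_before,window_after measurement windows.
#' @inheritParams synchrony_measure
#'
#' @return List with `S_before`, `S_after` and `diff` (`NA` and flagged if
#'   either window is undefined).
#' @export
delta_synchrony <- function(result, window_before = ingsim::window_before(),
                            window_after = ingsim::window_after(),
                            kernel_sd = 2, grid_step = 0.5, N = NULL) {
  s0 <- synchrony_measure(result, window_before, kernel_sd, grid_step, N)
  s1 <- synchrony_measure(result, window_after, kernel_sd, grid_step, N)
  d <- if (is.na(s0) || is.na(s1)) NA_real_ else as.numeric(s1) - as.numeric(s0)
  list(S_before = s0, S_after = s1, diff = d)
}

#' Bistability measure over a grid of synchrony differences
#'
#' Sum of the (seed-averaged) before/after synchrony differences that
#' strictly exceed the threshold.  Differences at or below the threshold
#' are excluded entirely: smaller increases typically reflect "tighter"
#' synchrony rather than a transition between dynamical states.  Undefined
#' entries (`NA`) are skipped and counted.
#'
#' @param diff_map numeric vector or matrix of synchrony differences.
#' @param threshold transition threshold (default 0.3).
#'
#' @return Non-negative numeric score with attribute `n_undefined`.
#' @export
bistability_measure <- function(diff_map, threshold = 0.3) {
  x <- as.numeric(diff_map)
  nas <- is.na(x)
  structure(sum(x[!nas & x > threshold]), n_undefined = sum(nas))
}

#' Mean firing frequency of a population
#'
#' Total spike count in the window divided by the population size and the
#' window length: the average per-cell firing rate in Hz.
#'
#' @inheritParams synchrony_measure
#'
#' @return Frequency in Hz (0 for a silent window).
#' @export
mean_firing_frequency <- function(raster, window = window_before(),
                                  N = NULL) {
  N <- raster_N(raster, N)
  df <- raster_df(raster)
  stopifnot(inherits(window, "measure_window"))
  nsp <- sum(df$time > window$t_start & df$time <= window$t_end)
  nsp / N / ((window$t_end - window$t_start) / 1000)
}

#' Classify a synchrony value
#'
#' Labels network activity `"synchronous"` when S strictly exceeds the
#' cutoff and `"asynchronous"` otherwise (an S exactly at the cutoff is
#' asynchronous).
#'
#' @param S synchrony value(s).
#' @param cutoff classification cutoff (default 0.25).
#'
#' @return Character vector of labels (`NA` where S is undefined).
#' @export
classify_synchrony <- function(S, cutoff = 0.25) {
  ifelse(is.na(S), NA_character_,
         ifelse(S > cutoff, "synchronous", "asynchronous"))
}

#' Sharpness of the asynchrony-to-synchrony transition
#'
#' Given synchrony values along an ascending, uniformly spaced applied
#' current axis (one synaptic-weight slice), locates the first point whose
#' S exceeds half the panel-wide maximum and returns the slope of the
#' segment joining it to the previous point.  The half-max reference is
#' panel-wide (supplied by the caller), not per slice.
#'
#' @param I_mu ascending applied-current values (pA), uniform step.
#' @param S synchrony values at those currents.
#' @param S_max_panel maximum synchrony observed anywhere in the panel.
#'
#' @return Slope in 1/pA, or `NA` with a `reason` attribute when no point
#'   exceeds half-max or the first point already does.
#' @export
transition_slope <- function(I_mu, S, S_max_panel) {
  stopifnot(length(I_mu) == length(S), length(I_mu) >= 2)
  if (any(diff(I_mu) <= 0)) stop("I_mu must be strictly ascending",
                                 call. = FALSE)
  steps <- diff(I_mu)
  if (max(steps) - min(steps) > 1e-8 * max(steps)) {
    stop("I_mu must be uniformly spaced", call. = FALSE)
  }
  k <- which(!is.na(S) & S > S_max_panel / 2)[1]
  if (is.na(k)) {
    return(structure(NA_real_, reason = "no point exceeds half-max"))
  }
  if (k == 1) {
    return(structure(NA_real_,
                     reason = "first point already exceeds half-max"))
  }
  if (is.na(S[k - 1])) {
    return(structure(NA_real_, reason = "preceding point undefined"))
  }
  (S[k] - S[k - 1]) / (I_mu[k] - I_mu[k - 1])
}
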