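#' Synthetic spike rasters with controlled coherence
#'
#' Generates spike rasters emulating the dynamical regimes seen in the
#' simulated networks, so synchrony and rate measures can be tested without
#' running the simulator:
#' \describe{
#'   \item{`synchronous`}{one shared periodic train at `rate` Hz copied to
#'     all N neurons (perfect coherence, S = 1).}
#'   \item{`jittered`}{the synchronous raster with i.i.d. Gaussian time
#'     jitter of SD `jitter_sd` ms per spike; jittered spikes falling
#'     outside the window are clipped to its edge.}
#'   \item{`poisson`}{N independent homogeneous Poisson trains at `rate` Hz
#'     (asynchronous surrogate).}
#'   \item{`clustered`}{`n_clusters` synchronous groups with phases spaced
#'     uniformly over one period.}
#'   \item{`silent`}{an empty raster.}
#' }
#' The periodic train starts half a period into the window.
#'
#' @param kind one of `"synchronous"`, `"jittered"`, `"poisson"`,
#'   `"clustered"`, `"silent"`.
#' @param N number of neurons.
#' @param rate firing rate (Hz), non-negative.
#' @param window a [measure_window()] the spikes are placed in.
#' @param jitter_sd jitter standard deviation (ms), for `"jittered"`.
#' @param n_clusters number of phase-shifted groups, for `"clustered"`.
#' @param seed RNG seed.
#'
#' @return Spike raster `data.frame` (`neuron`, `time`), sorted by neuron
#'   then time, with attributes `N` and `window`.
#' @export
make_raster <- function(kind = c("synchronous", "jittered", "poisson",
                                 "clustered", "silent"),
                        N = 500, rate = 30, window = window_before(),
                        jitter_sd = 0, n_clusters = 2, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(N >= 1, rate >= 0, jitter_sd >= 0, n_clusters >= 1,
            inherits(window, "measure_window"))
  w0 <- window$t_start
  w1 <- window$t_end
  base_train <- function(offset = 0) {
    if (rate == 0) return(numeric(0))
    period <- 1000 / rate
    ts <- seq(w0 + period / 2 + offset, w1, by = period)
    ts[ts > w0 & ts <= w1]
  }
  df <- switch(kind,
    silent = data.frame(neuron = integer(0), time = numeric(0)),
    synchronous = {
      ts <- base_train()
      data.frame(neuron = rep(seq_len(N), each = length(ts)),
                 time = rep(ts, times = N))
    },
    jittered = {
      ts <- base_train()
      local_seed_eval(seed, {
        times <- rep(ts, times = N) +
          rnorm(length(ts) * N, sd = jitter_sd)
        times <- pmin(pmax(times, w0 + 1e-9), w1)
        data.frame(neuron = rep(seq_len(N), each = length(ts)), time = times)
      })
    },
    poisson = {
      local_seed_eval(seed, {
        counts <- rpois(N, rate * (w1 - w0) / 1000)
        data.frame(neuron = rep(seq_len(N), times = counts),
                   time = runif(sum(counts), w0, w1))
      })
    },
    clustered = {
      period <- 1000 / max(rate, 1e-12)
      cl <- ((seq_len(N) - 1) %% n_clusters)
      parts <- lapply(seq_len(N), function(i) {
        ts <- base_train(offset = cl[i] * period / n_clusters)
        data.frame(neuron = rep.int(i, length(ts)), time = ts)
      })
      do.call(rbind, parts)
    })
  o <- order(df$neuron, df$time)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, N = as.integer(N), window = window)
}
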