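#' Network configuration
#'
#' Describes one randomly connected inhibitory network: population size,
#' connection probability, global synaptic weight, and the mean and
#' standard deviation of the heterogeneous tonic drive that stands in for
#' pyramidal-cell input.  Topology, drive and initial conditions are
#' controlled by three independent seeds so each can be varied in
#' isolation.
#'
#' @param N population size (default 500).
#' @param p_conn connection probability for each ordered pair of distinct
#'   neurons (the study used 0.04, 0.08, 0.12, 0.16).
#' @param g_syn synaptic weight shared by all connections (nS; study range
#'   0-10).
#' @param I_mu mean tonic applied current (pA; study range 100-1000).
#' @param sigma_I standard deviation of the tonic current (pA; the study
#'   used 3, 6 and 12).
#' @param seed_topology,seed_drive,seed_init independent RNG seeds.
#'
#' @return Object of class `network_config`.
#' @export
network_config <- function(N = 500, p_conn, g_syn, I_mu, sigma_I = 6,
                           seed_topology = 1, seed_drive = 2, seed_init = 3) {
  stop_if_not_finite(c(N, p_conn, g_syn, I_mu, sigma_I), "network_config")
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (p_conn < 0 || p_conn > 1) stop("p_conn must lie in [0, 1]",
                                     call. = FALSE)
  if (sigma_I < 0) stop("sigma_I must be non-negative", call. = FALSE)
  if (g_syn < 0) stop("g_syn must be non-negative", call. = FALSE)
  structure(list(N = as.integer(N), p_conn = p_conn, g_syn = g_syn,
                 I_mu = I_mu, sigma_I = sigma_I,
                 seed_topology = seed_topology, seed_drive = seed_drive,
                 seed_init = seed_init),
            class = "network_config")
}

#' Random directed connectivity
#'
#' Every ordered pair (i, j) of distinct neurons receives a directed edge
#' independently with probability `p_conn`.  Self-edges (autapses) are
#' excluded.  The draw is reproducible under `seed` and leaves the caller's
#' RNG state untouched.
#'
#' @param N number of neurons.
#' @param p_conn connection probability.
#' @param seed RNG seed.
#'
#' @return `data.frame` with integer columns `pre` and `post` (1-based),
#'   of class `connectivity`, carrying `N`, `p_conn` and `seed` attributes.
#' @export
build_connectivity <- function(N, p_conn, seed = 1) {
  stopifnot(N >= 2, p_conn >= 0, p_conn <= 1)
  N <- as.integer(N)
  pre <- rep(seq_len(N), each = N)
  post <- rep(seq_len(N), times = N)
  off <- pre != post
  pre <- pre[off]
  post <- post[off]
  keep <- local_seed_eval(seed, runif(length(pre)) < p_conn)
  edges <- data.frame(pre = pre[keep], post = post[keep])
  structure(edges, N = N, p_conn = p_conn, seed = seed,
            class = c("connectivity", "data.frame"))
}

#' Heterogeneous tonic drive vector
#'
#' Per-neuron tonic applied currents drawn i.i.d. from
#' Normal(`I_mu`, `sigma_I`^2) and held fixed for the entire simulation.
#' Draws are kept as drawn (no clipping of rare negative values).
#'
#' @param N number of neurons.
#' @param I_mu mean current (pA).
#' @param sigma_I standard deviation (pA).
#' @param seed RNG seed.
#'
#' @return Numeric vector of length `N` (pA).
#' @export
draw_drive <- function(N, I_mu, sigma_I, seed = 1) {
  stopifnot(N >= 1, sigma_I >= 0)
  local_seed_eval(seed, rnorm(N, mean = I_mu, sd = sigma_I))
}

#' Assemble a network from its configuration
#'
#' Draws the connectivity and the drive vector under the configuration's
#' seeds and bundles them with the configuration.
#'
#' @param config a [network_config()].
#'
#' @return Object of class `inh_network`: list with fields `config`,
#'   `connectivity` and `drive`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  conn <- build_connectivity(config$N, config$p_conn,
                             seed = config$seed_topology)
  drive <- draw_drive(config$N, config$I_mu, config$sigma_I,
                      seed = config$seed_drive)
  structure(list(config = config, connectivity = conn, drive = drive),
            class = "inh_network")
}

#' @export
print.inh_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Inhibitory network: N = %d, p_conn = %.3g ",
                     "(%d edges), g_syn = %.3g nS, ",
                     "I_mu = %.4g pA, sigma_I = %.3g pA\n"),
              cfg$N, cfg$p_conn, nrow(x$connectivity), cfg$g_syn,
              cfg$I_mu, cfg$sigma_I))
  invisible(x)
}
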