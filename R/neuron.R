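#' One forward-Euler step of a single neuron
#'
#' Reference (pure R) implementation of a single integration step of the
#' interneuron model.  The scaling factor k is selected from the pre-step
#' voltage (`k_low` for `V <= v_t`, `k_high` above).  If the post-update
#' voltage reaches `v_peak` the reset is applied within the same step and
#' the spike flag is raised.
#'
#' @param state list with fields `V` (mV) and `u` (pA).
#' @param p an [izhikevich_params()] object.
#' @param I_total total input current (pA): the signed sum
#'   `I_app + I_perturb - I_syn`.
#' @param dt time step (ms), positive.
#'
#' @return List with the updated `state` and logical `spiked`.
#' @export
neuron_step <- function(state, p, I_total, dt) {
  stopifnot(inherits(p, "izh_params"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive finite scalar", call. = FALSE)
  }
  stop_if_not_finite(c(state$V, state$u, I_total), "neuron state or input")
  k <- if (state$V <= p$v_t) p$k_low else p$k_high
  V <- state$V +
    dt * (k * (state$V - p$v_r) * (state$V - p$v_t) - state$u + I_total) / p$C_m
  u <- state$u + dt * p$a * (p$b * (state$V - p$v_r) - state$u)
  spiked <- FALSE
  if (V >= p$v_peak) {
    V <- p$c
    u <- u + p$d
    spiked <- TRUE
  }
  list(state = list(V = V, u = u), spiked = spiked)
}

#' Simulate an isolated neuron under constant current
#'
#' Fixed-step Euler integration of a single cell with a constant applied
#' current and no synaptic input, starting (by default) from rest
#' (`V = v_r`, `u = 0`).
#'
#' @param p an [izhikevich_params()] object.
#' @param I_app constant applied current (pA).
#' @param T simulation length (ms).
#' @param dt time step (ms).
#' @param V0,u0 initial conditions.
#'
#' @return Numeric vector of spike times (ms).
#' @export
simulate_neuron <- function(p, I_app, T = 2000, dt = 0.01, V0 = p$v_r,
                            u0 = 0) {
  stopifnot(inherits(p, "izh_params"))
  stop_if_not_finite(c(I_app, T, dt, V0, u0), "simulate_neuron inputs")
  if (dt <= 0 || T <= 0) stop("T and dt must be positive", call. = FALSE)
  sim_neuron_cpp(par_vec(p), I_app, T, dt, V0, u0)
}

#' Frequency-current (FI) curve from initial and final inter-spike intervals
#'
#' For each applied current the cell is simulated for `T` ms from rest and
#' two instantaneous frequencies are reported: `f_initial = 1000/ISI_first`
#' and `f_final = 1000/ISI_last`.  Their separation quantifies
#' spike-frequency adaptation.  Currents evoking fewer than two spikes
#' report both frequencies as 0; with exactly two spikes the single ISI is
#' used for both.
#'
#' @param p an [izhikevich_params()] object.
#' @param I_values applied currents to probe (pA); must be non-empty.
#' @param T simulation length per current (ms).
#' @param dt time step (ms).
#'
#' @return `data.frame` with columns `I_pA`, `f_initial_Hz`, `f_final_Hz`.
#' @export
fi_curve <- function(p, I_values, T = 2000, dt = 0.01) {
  if (length(I_values) == 0) stop("I_values must be non-empty", call. = FALSE)
  res <- vapply(I_values, function(I) {
    st <- simulate_neuron(p, I, T = T, dt = dt)
    if (length(st) < 2) return(c(0, 0))
    isi <- diff(st)
    c(1000 / isi[1], 1000 / isi[length(isi)])
  }, numeric(2))
  data.frame(I_pA = I_values, f_initial_Hz = res[1, ], f_final_Hz = res[2, ])
}

#' Rheobase by bisection
#'
#' Smallest constant current that evokes at least one spike within `T` ms,
#' located by bisection on the bracket to within `tol`.
#'
#' @param p an [izhikevich_params()] object.
#' @param tol absolute tolerance on the returned current (pA), positive.
#' @param T simulation length per probe (ms).
#' @param dt time step (ms).
#' @param bracket search interval (pA).
#'
#' @return Rheobase estimate in pA, or `NA` (with a warning) if no current
#'   in the bracket evokes a spike.
#' @export
find_rheobase <- function(p, tol = 0.5, T = 2000, dt = 0.01,
                          bracket = c(0, 1000)) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive", call. = FALSE)
  spikes_at <- function(I) length(simulate_neuron(p, I, T = T, dt = dt)) >= 1
  lo <- bracket[1]
  hi <- bracket[2]
  if (!spikes_at(hi)) {
    warning("no spiking found within the search bracket; rheobase not found")
    return(NA_real_)
  }
  if (spikes_at(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
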