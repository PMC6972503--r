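#' Kinetic parameters of the inhibitory synapse
#'
#' First-order kinetic synapse: a presynaptic spike releases a unitary
#' transmitter pulse of duration `T_dur`, during which the gating variable
#' `s` (fraction of open channels) relaxes toward
#' \eqn{s_\infty = \alpha/(\alpha+\beta)} with time constant
#' \eqn{\tau_s = 1/(\alpha+\beta)}; after the pulse `s` decays as
#' \eqn{e^{-\beta t}}.  The synaptic current onto a postsynaptic cell is
#' \eqn{I_{syn} = g_{syn} \, s \, (V - E_{syn})}, which enters the membrane
#' equation with a minus sign (positive values are hyperpolarizing for
#' \eqn{V > E_{syn}}).
#'
#' @param g_syn synaptic weight (nS), non-negative.
#' @param E_syn reversal potential (mV); -75 mV for all inhibitory synapses.
#' @param alpha inverse rise time constant (1/ms).
#' @param beta inverse decay time constant (1/ms).
#' @param T_dur transmitter pulse duration (ms).
#'
#' @return Object of class `synapse_params` with derived fields `s_inf`
#'   and `tau_s`.
#' @export
synapse_params <- function(g_syn = 1, E_syn = -75, alpha = 3.7037,
                           beta = 0.3333, T_dur = 1) {
  stop_if_not_finite(c(g_syn, E_syn, alpha, beta, T_dur), "synapse_params")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive",
                                    call. = FALSE)
  if (g_syn < 0) stop("g_syn must be non-negative", call. = FALSE)
  if (T_dur <= 0) stop("T_dur must be positive", call. = FALSE)
  structure(list(g_syn = g_syn, E_syn = E_syn, alpha = alpha, beta = beta,
                 T_dur = T_dur, s_inf = alpha / (alpha + beta),
                 tau_s = 1 / (alpha + beta)),
            class = "synapse_params")
}

#' Gate state of one presynaptic source
#'
#' All outgoing synapses of a cell share the same transmitter pulse and
#' kinetics, so a single gate per presynaptic neuron is maintained and
#' fanned out to its targets (mathematically identical to per-edge gates).
#'
#' @param s current open-channel fraction, in \[0, 1\].
#' @param t_onset time of the most recent transmitter-pulse onset (ms), or
#'   `NA` if no presynaptic spike has occurred yet.
#' @param s_onset gate value at pulse onset.
#'
#' @return Object of class `gate_state`.
#' @export
gate_state <- function(s = 0, t_onset = NA_real_, s_onset = s) {
  if (s < 0 || s > 1) stop("gate value s must lie in [0, 1]", call. = FALSE)
  structure(list(s = s, t_onset = t_onset, s_onset = s_onset),
            class = "gate_state")
}

#' Advance a synaptic gate to a new time
#'
#' Evaluates the closed-form gate trajectory at `t_now`.  Within `T_dur` of
#' the last presynaptic spike the gate follows the saturating rise
#' \eqn{s(t) = s_\infty + (s(t_0) - s_\infty) e^{-(t - t_0)/\tau_s}};
#' afterwards it decays as \eqn{s(t) = s(t_1) e^{-\beta (t - t_1)}} from its
#' value at pulse offset \eqn{t_1 = t_0 + T_{dur}}.  A new presynaptic spike
#' restarts the pulse clock with the current gate value as \eqn{s(t_0)},
#' preserving continuity.
#'
#' @param g a [gate_state()].
#' @param sp a [synapse_params()].
#' @param t_now current time (ms); must not decrease between calls.
#' @param presyn_spiked logical; did the presynaptic neuron spike at `t_now`?
#'
#' @return The updated `gate_state` at `t_now`.
#' @export
gate_update <- function(g, sp, t_now, presyn_spiked = FALSE) {
  stopifnot(inherits(g, "gate_state"), inherits(sp, "synapse_params"))
  stop_if_not_finite(t_now, "t_now")
  s <- if (is.na(g$t_onset)) {
    # never stimulated: pure decay from the initial value
    g$s * exp(-sp$beta * t_now)
  } else {
    elapsed <- t_now - g$t_onset
    if (elapsed < 0) stop("time must advance monotonically", call. = FALSE)
    if (elapsed <= sp$T_dur) {
      sp$s_inf + (g$s_onset - sp$s_inf) * exp(-elapsed / sp$tau_s)
    } else {
      s_t1 <- sp$s_inf + (g$s_onset - sp$s_inf) * exp(-sp$T_dur / sp$tau_s)
      s_t1 * exp(-sp$beta * (elapsed - sp$T_dur))
    }
  }
  if (isTRUE(presyn_spiked)) {
    gate_state(s = s, t_onset = t_now, s_onset = s)
  } else {
    gate_state(s = s, t_onset = g$t_onset, s_onset = g$s_onset)
  }
}

#' Total synaptic current onto one postsynaptic cell
#'
#' \eqn{I_{syn} = \sum_{j \in pre} g_{syn} \, s_j \, (V_{post} - E_{syn})},
#' summed over the incoming edges.  The returned value is the signed current
#' as written in the membrane equation, where it is subtracted; for an
#' inhibitory reversal below the membrane potential it is therefore
#' hyperpolarizing.
#'
#' @param V_post postsynaptic membrane potential (mV).
#' @param s_values gating values of all presynaptic sources (one per neuron).
#' @param g_syn synaptic weight (nS).
#' @param E_syn reversal potential (mV).
#' @param incoming indices into `s_values` of the presynaptic neurons with an
#'   edge onto this cell (possibly empty).
#'
#' @return Synaptic current in pA.
#' @export
synaptic_current <- function(V_post, s_values, g_syn, E_syn = -75,
                             incoming = seq_along(s_values)) {
  if (length(incoming) == 0) return(0)
  g_syn * sum(s_values[incoming]) * (V_post - E_syn)
}
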