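#' Stimulus protocol for a network simulation
#'
#' Timing constants of the standard protocol: a 2,000 ms run integrated at
#' dt = 0.01 ms, synapses inactive for the first 100 ms (so initial
#' transients decay), and a brief square current pulse delivered uniformly
#' to every cell to probe for a coexisting synchronous state.  The default
#' pulse is 1,000 pA for 2 ms at t = 1,000 ms.
#'
#' @param T_total simulation length (ms).
#' @param dt integration step (ms), in (0, 0.1].
#' @param synapse_enable_t time before which spikes trigger no synaptic
#'   transmitter pulse (ms).
#' @param perturb_amplitude perturbation amplitude (pA); 0 disables it.
#' @param perturb_width perturbation duration (ms).
#' @param perturb_onset perturbation onset (ms).
#'
#' @return Object of class `stim_protocol`.
#' @export
stimulus_protocol <- function(T_total = 2000, dt = 0.01,
                              synapse_enable_t = 100,
                              perturb_amplitude = 1000, perturb_width = 2,
                              perturb_onset = 1000) {
  stop_if_not_finite(c(T_total, dt, synapse_enable_t, perturb_amplitude,
                       perturb_width, perturb_onset), "stimulus_protocol")
  if (dt <= 0 || dt > 0.1) stop("dt must lie in (0, 0.1]", call. = FALSE)
  if (perturb_onset + perturb_width > T_total) {
    stop("perturbation must end within the simulation", call. = FALSE)
  }
  if (synapse_enable_t >= perturb_onset) {
    stop("synapse_enable_t must precede perturb_onset", call. = FALSE)
  }
  structure(list(T_total = T_total, dt = dt,
                 synapse_enable_t = synapse_enable_t,
                 perturb_amplitude = perturb_amplitude,
                 perturb_width = perturb_width,
                 perturb_onset = perturb_onset),
            class = "stim_protocol")
}

#' Protocol with the background-activity-derived pulse
#'
#' The standard protocol with the idealized 1,000 pA / 2 ms pulse replaced
#' by a 320 pA / 5 ms square pulse, the simplification of a transient
#' observed in Ornstein-Uhlenbeck background excitatory synaptic current.
#' All other timing constants keep their defaults.
#'
#' @return A [stimulus_protocol()].
#' @export
make_ou_pulse_protocol <- function() {
  stimulus_protocol(perturb_amplitude = 320, perturb_width = 5)
}

#' Ornstein-Uhlenbeck background-conductance parameters
#'
#' Mean-reverting stochastic model of background excitatory synaptic
#' conductance, with exact update
#' \deqn{g_e(t+h) = g_{e0} + [g_e(t) - g_{e0}] e^{-h/\tau_e} + A_e \, N(0,1)}
#' \deqn{A_e = \sqrt{\tfrac{D_e \tau_e}{2} \left(1 - e^{-2h/\tau_e}\right)}}
#' The stationary distribution has mean `g_e0` and variance
#' `D_e * tau_e / 2`.
#'
#' @param g_e0 mean conductance (nS).
#' @param tau_e correlation time (ms).
#' @param D_e unitless diffusion coefficient.
#' @param h update step (ms).
#' @param E_exc excitatory reversal potential (mV).
#' @param V_ref reference membrane potential used when converting
#'   conductance to current (mV); the resting potential of the interneuron
#'   models.
#'
#' @return Object of class `ou_params`, including the derived amplitude
#'   `A_e`.
#' @export
ou_params <- function(g_e0 = 3, tau_e = 2, D_e = 2, h = 0.01, E_exc = 0,
                      V_ref = -60.6) {
  stop_if_not_finite(c(g_e0, tau_e, D_e, h, E_exc, V_ref), "ou_params")
  if (tau_e <= 0 || h <= 0) stop("tau_e and h must be positive",
                                 call. = FALSE)
  if (D_e < 0) stop("D_e must be non-negative", call. = FALSE)
  A_e <- sqrt(D_e * tau_e / 2 * (1 - exp(-2 * h / tau_e)))
  structure(list(g_e0 = g_e0, tau_e = tau_e, D_e = D_e, h = h,
                 E_exc = E_exc, V_ref = V_ref, A_e = A_e),
            class = "ou_params")
}

#' Sample an Ornstein-Uhlenbeck conductance trace
#'
#' Exact-update recursion starting from `g_e(0) = g_e0`, reproducible under
#' `seed`.
#'
#' @param ou an [ou_params()] object.
#' @param T trace length (ms).
#' @param seed RNG seed.
#'
#' @return Numeric vector of conductances (nS) at times `0, h, 2h, ...`
#'   (length `floor(T/h) + 1`), with the step recorded in attribute `h`.
#' @export
ou_conductance <- function(ou, T, seed = 1) {
  stopifnot(inherits(ou, "ou_params"), T > 0)
  n <- floor(T / ou$h)
  rho <- exp(-ou$h / ou$tau_e)
  z <- local_seed_eval(seed, rnorm(n))
  # deviation x from the mean follows x_{t+1} = rho x_t + A_e z_t, x_0 = 0
  dev <- stats::filter(ou$A_e * z, rho, method = "recursive")
  g <- c(ou$g_e0, ou$g_e0 + as.numeric(dev))
  attr(g, "h") <- ou$h
  g
}

#' Convert excitatory conductance to a driving current
#'
#' Multiplies the conductance by the magnitude of the driving force
#' `|V_ref - E_exc|`, approximating the membrane potential by the resting
#' potential.  The result is a depolarizing-positive current suitable for
#' the applied-current channel of the membrane equation.
#'
#' @param g conductance (nS), scalar or vector.
#' @param ou an [ou_params()] object.
#'
#' @return Current(s) in pA.
#' @export
conductance_to_current <- function(g, ou) {
  stopifnot(inherits(ou, "ou_params"))
  g * abs(ou$V_ref - ou$E_exc)
}
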