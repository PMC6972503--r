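#' Single-neuron parameter set for the modified Izhikevich interneuron model
#'
#' Constructs and validates the ten parameters of the two-variable
#' interneuron model
#' \deqn{C_m \dot V = k(V - v_r)(V - v_t) - u - I_{syn} + I_{app} + I_{perturb}}
#' \deqn{\dot u = a[b(V - v_r) - u]}
#' with after-spike reset \eqn{V \leftarrow c}, \eqn{u \leftarrow u + d}
#' whenever \eqn{V \ge v_{peak}}, and piecewise scaling
#' \eqn{k = k_{low}} for \eqn{V \le v_t}, \eqn{k = k_{high}} otherwise.
#'
#' @param C_m membrane capacitance (pF), positive.
#' @param v_r resting membrane potential (mV).
#' @param v_t instantaneous threshold potential (mV), must exceed `v_r`.
#' @param v_peak spike cut-off voltage (mV), must exceed `v_t`.
#' @param a recovery-current time constant (1/ms), positive.
#' @param b sensitivity of the recovery current to subthreshold voltage (nS).
#' @param c after-spike reset voltage (mV), below `v_peak`.
#' @param d after-spike recovery-current increment (pA).
#' @param k_low subthreshold voltage-scaling factor (nS/mV), positive.
#' @param k_high suprathreshold voltage-scaling factor (nS/mV), positive.
#'
#' @return An object of class `izh_params` (named list).
#' @seealso [make_preset()] for the two named interneuron presets.
#' @export
izhikevich_params <- function(C_m, v_r, v_t, v_peak, a, b, c, d,
                              k_low, k_high) {
  p <- list(C_m = C_m, v_r = v_r, v_t = v_t, v_peak = v_peak, a = a,
            b = b, c = c, d = d, k_low = k_low, k_high = k_high)
  vals <- unlist(p)
  stop_if_not_finite(vals, "izhikevich_params")
  if (C_m <= 0 || k_low <= 0 || k_high <= 0 || a <= 0) {
    stop("C_m, a, k_low and k_high must all be positive", call. = FALSE)
  }
  if (!(v_r < v_t && v_t < v_peak)) {
    stop("require v_r < v_t < v_peak", call. = FALSE)
  }
  if (c >= v_peak) stop("reset voltage c must lie below v_peak", call. = FALSE)
  structure(p, class = "izh_params")
}

#' Named interneuron presets: control and 4-AP
#'
#' Returns the parameter set of either the control interneuron or the
#' hyperexcitable interneuron modelling treatment with 4-Aminopyridine
#' (4-AP), a potassium-channel blocker used as an acute seizure model.
#' The 4-AP preset has a smaller capacitance and subthreshold scaling and a
#' stronger adaptation increment, giving it a lower rheobase, a steeper FI
#' curve, and more pronounced spike-frequency adaptation than control.
#'
#' @param name `"control"` or `"four_ap"`.
#'
#' @return An [izhikevich_params()] object with a `preset` attribute.
#' @examples
#' make_preset("control")$C_m   # 73 pF
#' make_preset("four_ap")$b     # -0.4 nS
#' @export
make_preset <- function(name) {
  presets <- list(
    control = izhikevich_params(C_m = 73, v_r = -60.6, v_t = -43.1,
                                v_peak = 2.5, a = 0.01, b = -0.2, c = -67,
                                d = 0.75, k_low = 0.6, k_high = 2),
    four_ap = izhikevich_params(C_m = 49, v_r = -60.6, v_t = -43.1,
                                v_peak = 2.5, a = 0.01, b = -0.4, c = -67,
                                d = 1.25, k_low = 0.4, k_high = 2)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    stop(sprintf("unknown preset %s; valid presets: %s",
                 deparse(substitute(name)),
                 paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  p <- presets[[name]]
  attr(p, "preset") <- name
  p
}

#' @export
print.izh_params <- function(x, ...) {
  nm <- attr(x, "preset")
  cat("Izhikevich interneuron parameters",
      if (!is.null(nm)) sprintf("(preset: %s)", nm), "\n")
  units <- c(C_m = "pF", v_r = "mV", v_t = "mV", v_peak = "mV", a = "1/ms",
             b = "nS", c = "mV", d = "pA", k_low = "nS/mV", k_high = "nS/mV")
  for (f in names(units)) {
    cat(sprintf("  %-7s %8.3g %s\n", f, x[[f]], units[[f]]))
  }
  invisible(x)
}

# Fixed-order parameter vector consumed by the C++ integrators.
par_vec <- function(p) {
  stopifnot(inherits(p, "izh_params"))
  as.numeric(unlist(p[c("C_m", "v_r", "v_t", "v_peak", "a", "b", "c", "d",
                        "k_low", "k_high")]))
}
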