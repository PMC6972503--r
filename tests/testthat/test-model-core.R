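test_that("named presets carry the published parameter columns", {
  ctrl <- make_preset("control")
  fap <- make_preset("four_ap")
  expect_equal(ctrl[c("C_m", "b", "d", "k_low")],
               list(C_m = 73, b = -0.2, d = 0.75, k_low = 0.6))
  expect_equal(fap[c("C_m", "b", "d", "k_low")],
               list(C_m = 49, b = -0.4, d = 1.25, k_low = 0.4))
  # shared fields
  for (p in list(ctrl, fap)) {
    expect_equal(p[c("v_r", "v_t", "v_peak", "a", "c", "k_high")],
                 list(v_r = -60.6, v_t = -43.1, v_peak = 2.5, a = 0.01,
                      c = -67, k_high = 2))
  }
  expect_error(make_preset("pyramidal"), "control, four_ap")
})

test_that("parameter validation rejects inconsistent sets", {
  expect_error(izhikevich_params(-1, -60, -43, 2.5, 0.01, -0.2, -67, 1,
                                 0.6, 2), "positive")
  expect_error(izhikevich_params(73, -43, -60, 2.5, 0.01, -0.2, -67, 1,
                                 0.6, 2), "v_r < v_t")
  expect_error(izhikevich_params(73, -60, -43, 2.5, 0.01, -0.2, 5, 1,
                                 0.6, 2), "below v_peak")
})

test_that("rest with zero input is a fixed point of the neuron step", {
  p <- make_preset("control")
  st <- list(V = p$v_r, u = 0)
  for (i in 1:500) {
    out <- neuron_step(st, p, I_total = 0, dt = 0.01)
    st <- out$state
  }
  expect_identical(st$V, p$v_r)
  expect_identical(st$u, 0)
})

test_that("reset rule fires at the spike cutoff and increments u by d", {
  p <- make_preset("control")
  # a state guaranteed to cross v_peak in one step under strong drive
  out <- neuron_step(list(V = 2.4, u = 0), p, I_total = 5000, dt = 0.01)
  expect_true(out$spiked)
  expect_identical(out$state$V, -67)
  u_pre <- 0 + 0.01 * p$a * (p$b * (2.4 - p$v_r) - 0)
  expect_equal(out$state$u, u_pre + p$d)
  expect_error(neuron_step(list(V = NaN, u = 0), p, 0, 0.01), "non-finite")
  expect_error(neuron_step(list(V = -60, u = 0), p, 0, -0.01), "positive")
})

test_that("coarse-step integration matches a fine-timestep oracle", {
  # spike counts must agree exactly; timing agreement is asserted per
  # inter-spike interval (plus the first spike), because the small phase
  # error of explicit Euler accumulates linearly with the number of spikes
  # while each individual interval stays accurate
  compare_to_fine <- function(p, I, horizon = 600) {
    fast <- simulate_neuron(p, I, T = horizon, dt = 0.01)
    fine <- euler_fine_oracle(p, I, T = horizon, dt = 5e-4)
    expect_equal(length(fast), length(fine))
    expect_lt(abs(fast[1] - fine[1]), 0.5)
    expect_lt(max(abs(diff(fast) - diff(fine))), 0.5)
  }
  compare_to_fine(make_preset("control"), 400)
  compare_to_fine(make_preset("four_ap"), 150)
})

test_that("gate closed forms match their fixed points and the ODE oracle", {
  sp <- synapse_params()
  # at s_inf the rise equation is stationary for the pulse duration
  g <- gate_state(s = sp$s_inf)
  g <- gate_update(g, sp, t_now = 0, presyn_spiked = TRUE)
  g2 <- gate_update(g, sp, t_now = 0.7)
  expect_equal(g2$s, sp$s_inf)
  # post-pulse decay: with beta = 0.3333/ms the gate 3 ms after pulse end
  # is its end-of-pulse value times exp(-0.9999)
  spd <- synapse_params(beta = 0.3333)
  gp <- gate_update(gate_state(0), spd, t_now = 0, presyn_spiked = TRUE)
  s_t1 <- gate_update(gp, spd, t_now = spd$T_dur)$s
  expect_equal(gate_update(gp, spd, t_now = spd$T_dur + 3)$s,
               s_t1 * exp(-0.9999))
  # full 1 ms rise from 0 vs adaptive ODE integration
  skip_if_not_installed("deSolve")
  g0 <- gate_update(gate_state(s = 0), sp, t_now = 0, presyn_spiked = TRUE)
  g1 <- gate_update(g0, sp, t_now = sp$T_dur)
  expect_equal(g1$s, gate_rise_ode_oracle(0, sp$alpha, sp$beta, sp$T_dur),
               tolerance = 1e-6)
})

test_that("gate stays within [0, 1] for randomized spike trains", {
  sp <- synapse_params()
  withr::with_seed(42, {
    for (rep in 1:20) {
      times <- sort(runif(40, 0, 100))
      g <- gate_state()
      t_prev <- 0
      for (tt in times) {
        g <- gate_update(g, sp, t_now = tt, presyn_spiked = runif(1) < 0.5)
        expect_gte(g$s, 0)
        expect_lte(g$s, 1)
      }
    }
  })
})

test_that("synaptic current follows the driving-force arithmetic", {
  expect_identical(synaptic_current(-55, numeric(0), 2, incoming = integer(0)),
                   0)
  expect_equal(synaptic_current(-55, 1, g_syn = 2, E_syn = -75), 40)
  expect_equal(synaptic_current(-75, 0.8, g_syn = 5, E_syn = -75), 0)
  # multiple incoming edges sum
  expect_equal(synaptic_current(-55, c(0.5, 0.25, 0.9), g_syn = 2,
                                incoming = c(1, 2)), 2 * 0.75 * 20)
})

test_that("FI curves report initial/final ISI frequencies and adaptation", {
  fap <- make_preset("four_ap")
  ctrl <- make_preset("control")
  expect_error(fi_curve(fap, numeric(0)), "non-empty")
  fi <- fi_curve(fap, c(10, 60, 120, 300), T = 1000)
  expect_equal(fi$f_initial_Hz[1], 0)  # below rheobase
  expect_equal(fi$f_final_Hz[1], 0)
  supra <- fi$I_pA > 30
  expect_true(all(fi$f_final_Hz[supra] <= fi$f_initial_Hz[supra]))
  # hyperexcitable preset fires faster than control at matched drive
  fic <- fi_curve(ctrl, c(60, 120, 300), T = 1000)
  expect_true(all(fi$f_initial_Hz[-1] > fic$f_initial_Hz))
  # exactly two spikes: the single ISI defines both frequencies
  st <- simulate_neuron(ctrl, 47, T = 400)
  expect_length(st, 2)
  fi2 <- fi_curve(ctrl, 47, T = 400)
  expect_equal(fi2$f_initial_Hz, fi2$f_final_Hz)
  expect_equal(fi2$f_initial_Hz, 1000 / diff(st))
})

test_that("rheobase bisection honours its contract and the preset ordering", {
  ctrl <- make_preset("control")
  fap <- make_preset("four_ap")
  tol <- 0.5
  r_ctrl <- find_rheobase(ctrl, tol = tol, T = 500)
  r_fap <- find_rheobase(fap, tol = tol, T = 500)
  expect_lt(r_fap, r_ctrl)
  expect_length(simulate_neuron(ctrl, r_ctrl - tol, T = 500), 0)
  expect_gte(length(simulate_neuron(ctrl, r_ctrl + tol, T = 500)), 1)
  # 1 pA brute-force scan agrees within tolerance
  scan <- seq(floor(r_ctrl) - 3, ceiling(r_ctrl) + 3, by = 1)
  fires <- vapply(scan, function(I)
    length(simulate_neuron(ctrl, I, T = 500)) >= 1, logical(1))
  expect_lte(abs(scan[which(fires)[1]] - r_ctrl), 1 + tol)
  # bracket without spiking reports not-found
  expect_warning(r_na <- find_rheobase(ctrl, tol = tol, T = 500,
                                       bracket = c(0, 5)), "not found")
  expect_true(is.na(r_na))
})
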