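#' Specification of a (g_syn x I_mu) parameter sweep
#'
#' One heatmap panel: a grid of synaptic weights and mean drives for a
#' fixed preset, connection probability and drive heterogeneity, with each
#' cell simulated `n_seeds` times under independently derived seeds and the
#' synchrony scores seed-averaged.
#'
#' @param preset `"control"` or `"four_ap"`.
#' @param g_syn_values strictly increasing synaptic weights (nS).
#' @param I_mu_values strictly increasing mean drives (pA).
#' @param p_conn connection probability.
#' @param sigma_I drive standard deviation (pA).
#' @param N population size.
#' @param n_seeds independent simulations per cell (the study averaged 5).
#' @param protocol a [stimulus_protocol()].
#' @param synapse a [synapse_params()] providing the synaptic kinetics.
#' @param master_seed master seed from which all per-cell, per-replicate
#'   topology/drive/initial-condition seeds are derived deterministically.
#'
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(preset, g_syn_values, I_mu_values, p_conn,
                       sigma_I = 6, N = 500, n_seeds = 5,
                       protocol = stimulus_protocol(),
                       synapse = synapse_params(), master_seed = 1) {
  stopifnot(length(g_syn_values) >= 1, length(I_mu_values) >= 1,
            n_seeds >= 1)
  if (is.unsorted(g_syn_values, strictly = TRUE) ||
      is.unsorted(I_mu_values, strictly = TRUE)) {
    stop("grid axes must be strictly increasing", call. = FALSE)
  }
  params <- make_preset(preset)
  structure(list(preset = preset, params = params,
                 g_syn_values = g_syn_values, I_mu_values = I_mu_values,
                 p_conn = p_conn, sigma_I = sigma_I, N = as.integer(N),
                 n_seeds = as.integer(n_seeds), protocol = protocol,
                 synapse = synapse, master_seed = master_seed),
            class = "sweep_spec")
}

# Deterministic counter-based seed derivation: each (cell, replicate) gets
# three disjoint seeds (topology, drive, initial conditions), independent
# of execution order.  Supports up to 512 cells and 16 replicates.
derive_seeds <- function(master_seed, cell_index, replicate) {
  stopifnot(cell_index >= 1, cell_index <= 512, replicate >= 1,
            replicate <= 16)
  base <- (as.numeric(master_seed) %% 32767) * 65536 +
    (cell_index - 1) * 128 + (replicate - 1) * 8
  list(topology = base + 1, drive = base + 2, init = base + 3)
}

#' Run a parameter sweep
#'
#' Simulates every grid cell `n_seeds` times with fresh topology, drive and
#' initial conditions per replicate, computes the synchrony measure before
#' and after the perturbation and the mean firing frequency, and stores the
#' seed averages alongside every per-replicate value for audit.  Rows of
#' the matrices index `I_mu` (ascending), columns index `g_syn`.
#'
#' @param spec a [sweep_spec()].
#' @param kernel_sd,grid_step convolution settings forwarded to
#'   [synchrony_measure()].
#'
#' @return Object of class `heatmap_grid`: axes, seed-averaged matrices
#'   `S_before`, `S_after`, `diff`, `mff` (firing frequency over the
#'   random-initial-conditions window, Hz), per-replicate arrays
#'   `*_seeds`, and panel metadata.
#' @export
run_sweep <- function(spec, kernel_sd = 2, grid_step = 0.5) {
  stopifnot(inherits(spec, "sweep_spec"))
  nI <- length(spec$I_mu_values)
  nG <- length(spec$g_syn_values)
  if (nI * nG > 512) stop("grid too large for the seed-derivation scheme",
                          call. = FALSE)
  dims <- c(nI, nG, spec$n_seeds)
  S_before <- S_after <- mff <- array(NA_real_, dims)
  for (gi in seq_len(nG)) {
    for (ii in seq_len(nI)) {
      cell <- (gi - 1) * nI + ii
      for (r in seq_len(spec$n_seeds)) {
        sds <- derive_seeds(spec$master_seed, cell, r)
        cfg <- network_config(N = spec$N, p_conn = spec$p_conn,
                              g_syn = spec$g_syn_values[gi],
                              I_mu = spec$I_mu_values[ii],
                              sigma_I = spec$sigma_I,
                              seed_topology = sds$topology,
                              seed_drive = sds$drive, seed_init = sds$init)
        res <- tryCatch(
          simulate(cfg, spec$params, spec$synapse, spec$protocol),
          error = function(e) NULL)
        if (is.null(res)) next
        d <- delta_synchrony(res, kernel_sd = kernel_sd,
                             grid_step = grid_step)
        S_before[ii, gi, r] <- as.numeric(d$S_before)
        S_after[ii, gi, r] <- as.numeric(d$S_after)
        mff[ii, gi, r] <- mean_firing_frequency(res)
      }
    }
  }
  avg <- function(a) apply(a, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  Sb <- avg(S_before)
  Sa <- avg(S_after)
  dimn <- list(I_mu = spec$I_mu_values, g_syn = spec$g_syn_values)
  dimnames(Sb) <- dimnames(Sa) <- dimn
  structure(list(g_syn_values = spec$g_syn_values,
                 I_mu_values = spec$I_mu_values,
                 S_before = Sb, S_after = Sa, diff = Sa - Sb,
                 mff = avg(mff),
                 S_before_seeds = S_before, S_after_seeds = S_after,
                 mff_seeds = mff,
                 preset = spec$preset, p_conn = spec$p_conn,
                 sigma_I = spec$sigma_I, N = spec$N,
                 n_seeds = spec$n_seeds, master_seed = spec$master_seed),
            class = "heatmap_grid")
}

#' Bistability scores of two matched panels
#'
#' Applies [bistability_measure()] to the seed-averaged synchrony
#' difference maps of two sweeps computed over identical axes (typically a
#' control panel and a 4-AP panel).
#'
#' @param grid_a,grid_b `heatmap_grid` objects with identical axes.
#' @param threshold transition threshold.
#'
#' @return Named numeric vector of the two scores (names taken from each
#'   panel's preset).
#' @export
compare_panels <- function(grid_a, grid_b, threshold = 0.3) {
  stopifnot(inherits(grid_a, "heatmap_grid"), inherits(grid_b, "heatmap_grid"))
  if (!isTRUE(all.equal(grid_a$g_syn_values, grid_b$g_syn_values)) ||
      !isTRUE(all.equal(grid_a$I_mu_values, grid_b$I_mu_values))) {
    stop("panels must share identical axes", call. = FALSE)
  }
  out <- c(as.numeric(bistability_measure(grid_a$diff, threshold)),
           as.numeric(bistability_measure(grid_b$diff, threshold)))
  names(out) <- c(grid_a$preset, grid_b$preset)
  out
}

#' Transition-slope table for matched control / 4-AP panels
#'
#' For each requested synaptic-weight slice, applies [transition_slope()]
#' to the random-initial-conditions synchrony column of each panel, using
#' that panel's panel-wide maximum as the half-max reference.
#'
#' @param grid_control,grid_4ap `heatmap_grid` objects with identical axes.
#' @param g_syn_slices synaptic weights to report (must be axis values).
#'
#' @return `data.frame` with columns `p_conn`, `sigma_I`, `g_syn`,
#'   `control_slope`, `fourap_slope` (1/pA, `NA` where undefined).
#' @export
slope_table <- function(grid_control, grid_4ap,
                        g_syn_slices = grid_control$g_syn_values) {
  stopifnot(inherits(grid_control, "heatmap_grid"),
            inherits(grid_4ap, "heatmap_grid"))
  slice_slope <- function(grid, g) {
    gi <- which(abs(grid$g_syn_values - g) < 1e-9)
    if (length(gi) != 1) stop(sprintf("g_syn = %g is not a grid column", g),
                              call. = FALSE)
    smax <- max(grid$S_before, na.rm = TRUE)
    as.numeric(transition_slope(grid$I_mu_values, grid$S_before[, gi], smax))
  }
  data.frame(
    p_conn = grid_control$p_conn, sigma_I = grid_control$sigma_I,
    g_syn = g_syn_slices,
    control_slope = vapply(g_syn_slices, slice_slope, numeric(1),
                           grid = grid_control),
    fourap_slope = vapply(g_syn_slices, slice_slope, numeric(1),
                          grid = grid_4ap))
}

#' Border of the synchronous regime on a sweep panel
#'
#' For each synaptic-weight column, the lowest mean drive whose
#' seed-averaged random-initial-conditions synchrony is classified
#' synchronous (S strictly above the cutoff).  Columns with no synchronous
#' cell are omitted.
#'
#' @param grid a `heatmap_grid`.
#' @param cutoff synchrony classification cutoff.
#'
#' @return `data.frame` with columns `g_syn` and `I_mu` (the border
#'   polyline), possibly empty.
#' @export
synchrony_border <- function(grid, cutoff = 0.25) {
  stopifnot(inherits(grid, "heatmap_grid"))
  rows <- lapply(seq_along(grid$g_syn_values), function(gi) {
    sync <- classify_synchrony(grid$S_before[, gi], cutoff) == "synchronous"
    k <- which(!is.na(sync) & sync)[1]
    if (is.na(k)) return(NULL)
    data.frame(g_syn = grid$g_syn_values[gi], I_mu = grid$I_mu_values[k])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(g_syn = numeric(0), I_mu = numeric(0))
  out
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf(paste0("Sweep panel (%s): %d x %d grid ",
                     "(I_mu %g-%g pA, g_syn %g-%g nS), p_conn = %g, ",
                     "sigma_I = %g, %d seed(s)\n"),
              x$preset, length(x$I_mu_values), length(x$g_syn_values),
              min(x$I_mu_values), max(x$I_mu_values), min(x$g_syn_values),
              max(x$g_syn_values), x$p_conn, x$sigma_I, x$n_seeds))
  cat(sprintf("Bistability measure (threshold 0.3): %.3f\n",
              as.numeric(bistability_measure(x$diff))))
  invisible(x)
}
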