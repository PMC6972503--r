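test_that("synchrony is exactly 1 for identical spike trains", {
  r <- make_raster("synchronous", N = 500, rate = 30)
  expect_equal(as.numeric(synchrony_measure(r)), 1, tolerance = 1e-12)
  # one neuron with at least two spikes is trivially synchronous with itself
  r1 <- make_raster("synchronous", N = 1, rate = 30)
  expect_equal(as.numeric(synchrony_measure(r1)), 1, tolerance = 1e-12)
})

test_that("independent Poisson trains score deep in the asynchronous regime", {
  r <- make_raster("poisson", N = 500, rate = 30, seed = 101)
  expect_lt(as.numeric(synchrony_measure(r)), 0.25)
})

test_that("the fast convolution path matches the brute-force definition", {
  # tolerance 1e-7: at the +/-5 SD truncation edge the two paths may
  # disagree on including a kernel value of order dnorm(5 SD) ~ 1e-6 when
  # a spike sits exactly one ulp across the boundary
  w <- window_before()
  for (kind in c("poisson", "clustered", "jittered")) {
    r <- make_raster(kind, N = 40, rate = 20, jitter_sd = 4, n_clusters = 2,
                     seed = 33)
    expect_equal(as.numeric(synchrony_measure(r, w)),
                 synchrony_brute_oracle(r, 40, w), tolerance = 1e-7,
                 info = kind)
  }
  # antiphase half-populations (the two-cluster fixture) against the oracle
  r2 <- make_raster("clustered", N = 100, rate = 30, n_clusters = 2)
  expect_equal(as.numeric(synchrony_measure(r2, w)),
               synchrony_brute_oracle(r2, 100, w), tolerance = 1e-7)
})

test_that("silent windows make the measure undefined, never zero", {
  r <- make_raster("silent", N = 20)
  s <- synchrony_measure(r)
  expect_true(is.na(s))
  expect_match(attr(s, "reason"), "silent")
  # silent neurons are excluded from the denominator and counted
  r2 <- make_raster("synchronous", N = 10, rate = 30)
  r2 <- r2[r2$neuron <= 6, ]
  attr(r2, "N") <- 10L
  s2 <- synchrony_measure(r2)
  expect_equal(attr(s2, "excluded"), 4)
  expect_gt(as.numeric(s2), 0)
})

test_that("synchrony is invariant to relabeling and in-window time shifts", {
  w <- window_before()
  r <- make_raster("poisson", N = 60, rate = 25, seed = 9,
                   window = measure_window(520, 980))
  attr(r, "N") <- 60L
  s0 <- as.numeric(synchrony_measure(r, w, N = 60))
  perm <- withr::with_seed(1, sample(60))
  r_perm <- r
  r_perm$neuron <- perm[r$neuron]
  r_perm <- r_perm[order(r_perm$neuron, r_perm$time), ]
  expect_equal(as.numeric(synchrony_measure(r_perm, w, N = 60)), s0,
               tolerance = 1e-12)
  r_shift <- r
  r_shift$time <- r$time + 5  # grid-aligned shift, spikes stay interior
  expect_equal(as.numeric(synchrony_measure(r_shift, w, N = 60)), s0,
               tolerance = 1e-9)
})

test_that("synchrony degrades monotonically with jitter", {
  sds <- c(0, 2, 5, 10, 20)
  mean_s <- vapply(sds, function(j) {
    mean(vapply(1:10, function(seed) {
      r <- make_raster("jittered", N = 80, rate = 30, jitter_sd = j,
                       seed = seed)
      as.numeric(synchrony_measure(r))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_s) <= 1e-6))
  expect_equal(mean_s[1], 1, tolerance = 1e-12)
})

test_that("synchrony is robust to the evaluation grid step", {
  for (kind in c("poisson", "clustered")) {
    r <- make_raster(kind, N = 60, rate = 30, seed = 4)
    s_coarse <- as.numeric(synchrony_measure(r, grid_step = 0.5))
    s_fine <- as.numeric(synchrony_measure(r, grid_step = 0.1))
    expect_lt(abs(s_coarse - s_fine), 0.02)
  }
})

test_that("synchrony difference composes and propagates undefined windows", {
  # same dynamics in both windows: difference 0
  r <- rbind(make_raster("poisson", N = 30, rate = 20, seed = 5),
             local({
               x <- make_raster("poisson", N = 30, rate = 20, seed = 5)
               x$time <- x$time + 1000
               x
             }))
  attr(r, "N") <- 30L
  d <- delta_synchrony(r, N = 30)
  expect_equal(d$diff, 0, tolerance = 1e-12)
  # silent pre-window flags the difference as undefined
  r2 <- make_raster("poisson", N = 30, rate = 20, seed = 5,
                    window = measure_window(1500, 2000))
  d2 <- delta_synchrony(r2, N = 30)
  expect_true(is.na(d2$diff))
  expect_true(is.na(d2$S_before))
  expect_false(is.na(d2$S_after))
})

test_that("bistability score filters then sums, skipping undefined cells", {
  expect_equal(as.numeric(bistability_measure(c(0.1, 0.3, 0.29))), 0)
  expect_equal(as.numeric(bistability_measure(c(0.5, 0.2, 0.31))), 0.81)
  b <- bistability_measure(c(0.5, NA, 0.6, NA))
  expect_equal(as.numeric(b), 1.1)
  expect_equal(attr(b, "n_undefined"), 2)
  withr::with_seed(10, {
    for (i in 1:20) {
      m <- matrix(runif(24, -0.2, 0.8), 4)
      m[sample(24, 3)] <- NA
      expect_equal(as.numeric(bistability_measure(m)),
                   bistability_brute_oracle(m))
    }
  })
  # non-negative and monotone in any entry
  m <- matrix(c(0.1, 0.4, 0.35, 0.2), 2)
  expect_gte(as.numeric(bistability_measure(m)), 0)
  m2 <- m
  m2[1, 1] <- 0.9
  expect_gte(as.numeric(bistability_measure(m2)),
             as.numeric(bistability_measure(m)))
})

test_that("mean firing frequency is the spike count rate per cell", {
  w <- window_before()
  expect_equal(mean_firing_frequency(make_raster("silent", N = 10), w), 0)
  # 500 cells x 10 spikes over 500 ms -> 20 Hz
  r <- make_raster("synchronous", N = 500, rate = 20)
  expect_equal(sum(r$time > 500 & r$time <= 1000) / 500, 10)
  expect_equal(mean_firing_frequency(r, w), 20)
  # equals the average of per-neuron rates
  rp <- make_raster("poisson", N = 80, rate = 25, seed = 2)
  per_neuron <- tabulate(rp$neuron, nbins = 80) / 0.5
  expect_equal(mean_firing_frequency(rp, w), mean(per_neuron))
  # additive over disjoint windows, weighted by length
  w1 <- measure_window(500, 700)
  w2 <- measure_window(700, 1000)
  f <- (mean_firing_frequency(rp, w1) * 200 +
          mean_firing_frequency(rp, w2) * 300) / 500
  expect_equal(mean_firing_frequency(rp, w), f)
})

test_that("classification uses a strict cutoff", {
  expect_equal(classify_synchrony(0.1), "asynchronous")
  expect_equal(classify_synchrony(0.8), "synchronous")
  expect_equal(classify_synchrony(0.25), "asynchronous")
  expect_equal(classify_synchrony(0.250001), "synchronous")
  expect_true(is.na(classify_synchrony(NA_real_)))
})

test_that("transition slope applies the half-max segment rule", {
  I <- seq(100, 250, by = 25)
  S <- c(0, 0, 0, 0.8, 0.82, 0.81, 0.8)
  expect_equal(as.numeric(transition_slope(I, S, 0.8)), 0.8 / 25)
  expect_equal(0.8 / 25, 0.032)
  # monotone but never above half-max: undefined
  s_lo <- transition_slope(I, seq(0, 0.3, length.out = 7), 0.8)
  expect_true(is.na(s_lo))
  expect_match(attr(s_lo, "reason"), "half-max")
  # first point above half-max: undefined
  expect_true(is.na(transition_slope(I, rep(0.9, 7), 0.9)))
  # synthetic sigmoids agree with the exhaustive scan oracle
  withr::with_seed(3, {
    for (i in 1:20) {
      I <- seq(100, 400, by = 5)
      mid <- runif(1, 150, 350)
      sc <- runif(1, 2, 40)
      S <- 0.85 / (1 + exp(-(I - mid) / sc))
      smax <- max(S) * runif(1, 1, 1.3)
      expect_equal(as.numeric(transition_slope(I, S, smax)),
                   slope_scan_oracle(I, S, smax))
    }
  })
  expect_error(transition_slope(c(1, 2, 4), c(0, 0, 1), 1), "uniform")
  expect_error(transition_slope(c(2, 1, 0), c(0, 0, 1), 1), "ascending")
})
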