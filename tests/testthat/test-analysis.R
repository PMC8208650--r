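# Circular phase statistics and the SPIKE dissimilarity measure.

test_that("spike phase wraps the accumulated drive phase", {
  d <- theta_drive(freq = 8, phase = 0)
  expect_equal(spike_phase(0, d), 0)
  expect_equal(spike_phase(31.25, d), pi / 2)
  expect_equal(spike_phase(125, d), 0, tolerance = 1e-9)   # one full cycle
  expect_equal(spike_phase(187.5, d), pi, tolerance = 1e-9)
  dp <- theta_drive(freq = 8, phase = pi)
  expect_equal(spike_phase(0, dp), pi)
})

test_that("phase histogram counts, mean and resultant behave", {
  ph <- c(0.1, 0.1, 0.1, pi)
  h <- phase_histogram(ph, n_bins = 8)
  expect_equal(sum(h$count), 4)
  expect_equal(nrow(h), 8)
  expect_equal(h$bin_center[1], pi / 8)
  # concentrated sample: resultant near 1, mean near the sample
  h2 <- phase_histogram(rep(1.3, 50))
  expect_equal(attr(h2, "circ_mean"), 1.3, tolerance = 1e-9)
  expect_equal(attr(h2, "resultant"), 1, tolerance = 1e-9)
  # evenly spread phases: resultant collapses to zero
  h3 <- phase_histogram(seq(0, 2 * pi, length.out = 401)[-401])
  expect_lt(attr(h3, "resultant"), 1e-10)
  # empty input
  h0 <- phase_histogram(numeric(0))
  expect_equal(sum(h0$count), 0)
  expect_true(is.na(attr(h0, "circ_mean")))
  expect_error(phase_histogram(1, n_bins = 2), "n_bins")
})

test_that("SPIKE dissimilarity is zero only for identical trains", {
  iv <- c(0, 1000)
  a <- c(100, 300, 550, 890)
  expect_equal(spike_train_distance(a, a, iv), 0)
  expect_equal(spike_train_distance(numeric(0), numeric(0), iv), 0)
  expect_gt(spike_train_distance(a, a + 20, iv), 0)
  expect_gt(spike_train_distance(a, numeric(0), iv), 0)
})

test_that("SPIKE dissimilarity is symmetric and bounded in [0, 1]", {
  fx <- generate_fixtures("poisson_pair", seed = 3)
  d1 <- spike_train_distance(fx$a, fx$b, fx$interval)
  d2 <- spike_train_distance(fx$b, fx$a, fx$interval)
  expect_equal(d1, d2, tolerance = 1e-12)
  for (s in 1:20) {
    fx <- generate_fixtures("poisson_pair", seed = s)
    d <- spike_train_distance(fx$a, fx$b, fx$interval)
    expect_gte(d, 0)
    expect_lte(d, 1)
  }
})

test_that("the worked two-spike example matches the grid profile", {
  fx <- generate_fixtures("two_spike_toy")
  d <- spike_train_distance(fx$a, fx$b, fx$interval)
  tt <- seq(0.0005, 99.9995, by = 0.001)
  g <- spike_profile_grid(fx$a, fx$b, fx$interval, tt)
  expect_equal(d, mean(g$S), tolerance = 1e-4)
  expect_gt(d, 0.05)
  expect_lt(d, 0.5)
})

test_that("exact piecewise average matches brute-force grids on random pairs", {
  worst <- 0
  for (s in 1:25) {
    rng_a <- generate_fixtures("poisson_pair", seed = s)
    a <- rng_a$a[rng_a$a <= 100]
    b <- rng_a$b[rng_a$b <= 100]
    iv <- c(0, 100)
    d <- spike_train_distance(a, b, iv)
    tt <- seq(0.0005, 99.9995, by = 0.001)
    g <- mean(spike_profile_grid(a, b, iv, tt)$S)
    worst <- max(worst, abs(d - g))
  }
  expect_lt(worst, 1e-4)
})

test_that("time-translation leaves the dissimilarity unchanged", {
  fx <- generate_fixtures("poisson_pair", seed = 9)
  d0 <- spike_train_distance(fx$a, fx$b, fx$interval)
  d1 <- spike_train_distance(fx$a + 500, fx$b + 500, fx$interval + 500)
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("reliability summarises pairwise distances per neuron", {
  # three identical trials: distance zero, three pairs
  sp <- tibble::tibble(trial = rep(1:3, each = 2),
                       neuron = 1L,
                       cell_type = "interneuron",
                       time = rep(c(100, 400), 3))
  r <- reliability(sp, subset = 1, interval = c(0, 500))
  expect_equal(r$mean_distance, 0)
  expect_equal(r$n_pairs, 3)
  # relabelling trials does not change the mean over unordered pairs
  sp2 <- sp
  sp2$time[sp2$trial == 2] <- c(150, 420)
  r_a <- reliability(sp2, 1, c(0, 500))
  sp3 <- sp2
  sp3$trial <- c(2L, 3L, 1L)[sp2$trial]
  r_b <- reliability(sp3, 1, c(0, 500))
  expect_equal(r_a$mean_distance, r_b$mean_distance, tolerance = 1e-12)
  expect_error(reliability(sp[sp$trial == 1, ], 1, c(0, 500)), "2 trials")
})

test_that("rate map integrates to the mean spike count per trial", {
  sp <- tibble::tibble(trial = rep(1:2, each = 3),
                       neuron = 5L, cell_type = "stellate",
                       time = c(300, 500, 700, 310, 505, 690))
  rm <- rate_map(sp, neuron = 5, sigma = 10, duration = 1000, dt = 0.5)
  integral <- sum(rm$rate) * 0.5
  expect_equal(integral, 3, tolerance = 0.01)
  # absent neuron gives a flat zero map
  rm0 <- rate_map(sp, neuron = 99, sigma = 10, duration = 1000)
  expect_true(all(rm0$rate == 0))
})
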