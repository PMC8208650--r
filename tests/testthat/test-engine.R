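# Integration engine: determinism, closed-form oracles, discretization
# accuracy and an independent-solver cross-check.

test_that("simulation is bitwise deterministic under a fixed seed", {
  net <- build_motif()
  prog <- stimulus_program(noise = noise_spec())
  cfg <- simulation_config(duration = 500)
  a <- integrate_network(net, prog, cfg, trial_seed = 42)
  b <- integrate_network(net, prog, cfg, trial_seed = 42)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$final_v, b$final_v)
  c <- integrate_network(net, prog, cfg, trial_seed = 43)
  expect_false(identical(a$final_v, c$final_v))
})

test_that("passive membrane relaxes along the closed-form exponential", {
  p <- default_net_params(stellate = stellate_params(g_na = 0, g_k = 0,
                                                     g_nap = 0, g_h = 0))
  net <- build_isolated("stellate", drive = 0, params = p)
  cfg <- simulation_config(duration = 20, record = 1, record_dt = 1,
                           init_v = -75)
  sim <- integrate_network(net, stimulus_program(noise = noise_spec(g_amp = 0)),
                           cfg, trial_seed = 1)
  # dV/dt = -g_leak (V - e_leak) / c_m  =>  tau = c_m / g_leak = 3 ms
  expected <- -65 + (-75 + 65) * exp(-sim$traces$time / 3)
  expect_equal(sim$traces$v, expected, tolerance = 1e-3)
  cfg$method <- "rk4"
  sim4 <- integrate_network(net, stimulus_program(noise = noise_spec(g_amp = 0)),
                            cfg, trial_seed = 1)
  expect_equal(sim4$traces$v, expected, tolerance = 1e-9)
})

test_that("gate clamping never triggers in normal operation", {
  sim <- integrate_network(build_motif(), stimulus_program(noise = noise_spec()),
                           simulation_config(duration = 500), trial_seed = 5)
  expect_equal(sim$clamp_count, 0)
})

test_that("numerical divergence raises an informative error", {
  net <- build_isolated("interneuron", drive = 1e6)
  expect_error(
    integrate_network(net, stimulus_program(noise = noise_spec(g_amp = 0)),
                      simulation_config(duration = 10), trial_seed = 1),
    "divergence")
})

test_that("spike detection interpolates crossings and enforces refractoriness", {
  tt <- seq(0, 10, by = 0.1)
  v <- -60 + 80 * (tt >= 5)  # step crossing between samples 4.9 and 5.0
  st <- detect_spikes(tt, v, threshold = 0, refractory = 2)
  expect_length(st, 1)
  expect_true(st > 4.9 && st <= 5.0)
  # linear ramp crossing zero exactly at t = 5
  st2 <- detect_spikes(tt, -50 + 10 * tt, threshold = 0)
  expect_equal(st2, 5, tolerance = 1e-9)
  # two crossings 1 ms apart collapse under a 2 ms refractory window
  v3 <- rep(-60, length(tt))
  v3[tt >= 3 & tt < 3.3] <- 10
  v3[tt >= 4 & tt < 4.3] <- 10
  expect_length(detect_spikes(tt, v3, refractory = 2), 1)
  expect_length(detect_spikes(tt, v3, refractory = 0.5), 2)
  expect_length(detect_spikes(numeric(0), numeric(0)), 0)
})

test_that("run_trials with one trial reproduces a single integration", {
  net <- build_motif()
  prog <- stimulus_program(noise = noise_spec())
  cfg <- simulation_config(duration = 400, n_trials = 1, seed = 9)
  one <- integrate_network(net, prog, cfg, trial_seed = 9)
  multi <- run_trials(net, prog, cfg)
  expect_equal(multi$spikes, one$spikes)
})

test_that("trial seeds only re-draw noise and initial conditions", {
  net <- build_ring(n_stellate = 8, n_interneuron = 8, seed = 4)
  prog <- stimulus_program(noise = noise_spec(g_amp = 0))
  cfg <- simulation_config(duration = 300, init_v = rep(-64, 16))
  a <- integrate_network(net, prog, cfg, trial_seed = 1)
  b <- integrate_network(net, prog, cfg, trial_seed = 999)
  # deterministic dynamics: different trial seeds change nothing
  expect_equal(a$spikes$time, b$spikes$time)
  expect_equal(a$final_v, b$final_v)
})

test_that("recorded traces respect the requested sampling and subset", {
  net <- build_motif()
  sim <- integrate_network(net, stimulus_program(noise = noise_spec()),
                           simulation_config(duration = 100, record = c(1, 3),
                                             record_dt = 0.5), trial_seed = 2)
  expect_equal(sort(unique(sim$traces$neuron)), c(1, 3))
  tt <- sort(unique(sim$traces$time))
  expect_equal(diff(tt), rep(0.5, length(tt) - 1), tolerance = 1e-9)
})

test_that("isolated stellate spike times converge to the reference integrator", {
  net <- build_isolated("stellate", drive = -1.5)
  prog <- stimulus_program(noise = noise_spec(g_amp = 0))
  cfg <- simulation_config(duration = 1000, init_v = -60)
  eu <- integrate_network(net, prog, cfg, trial_seed = 1)
  rk <- reference_integrate(net, prog, cfg, dt_ref = 0.001, trial_seed = 1)
  expect_equal(nrow(eu$spikes), nrow(rk$spikes))
  expect_gt(nrow(eu$spikes), 2)
  expect_lt(max(abs(eu$spikes$time - rk$spikes$time)), 1)
})

test_that("the reference integrator is self-convergent", {
  net <- build_isolated("stellate", drive = -1.5)
  prog <- stimulus_program(noise = noise_spec(g_amp = 0))
  cfg <- function(dt) simulation_config(dt = dt, duration = 600,
                                        method = "rk4", init_v = -60)
  a <- integrate_network(net, prog, cfg(0.002), trial_seed = 1)
  b <- integrate_network(net, prog, cfg(0.001), trial_seed = 1)
  expect_equal(nrow(a$spikes), nrow(b$spikes))
  expect_lt(max(abs(a$spikes$time - b$spikes$time)), 0.05)
})

test_that("motif regime survives the integrator choice", {
  net <- build_motif()
  prog <- stimulus_program(noise = noise_spec(g_amp = 0))
  base <- simulation_config(duration = 2000, init_v = I(c(-65, -65, -62, -66)))
  rk <- base; rk$method <- "rk4"; rk$dt <- 0.005
  # I() marks a per-cell vector; 4 cells need no marker but keep it uniform
  base$init_v <- c(-65, -65, -62, -66)
  rk$init_v <- c(-65, -65, -62, -66)
  eu <- integrate_network(net, prog, base, trial_seed = 1)
  r4 <- integrate_network(net, prog, rk, trial_seed = 1)
  sw_eu <- length(spike_train(eu, 3)) + length(spike_train(eu, 4))
  sw_r4 <- length(spike_train(r4, 3)) + length(spike_train(r4, 4))
  # same alternating regime: equal interneuron spike counts
  expect_equal(sw_eu, sw_r4)
})

test_that("pure-R derivatives integrated by an independent solver match the engine", {
  skip_if_not_installed("deSolve")
  p <- default_net_params()
  net <- build_isolated("stellate", drive = -2.7, params = p)
  cfg <- simulation_config(duration = 200, method = "rk4", record = 1,
                           record_dt = 1, init_v = -60)
  sim <- integrate_network(net, stimulus_program(noise = noise_spec(g_amp = 0)),
                           cfg, trial_seed = 1)
  ss <- steady_state(-60, "stellate")
  y0 <- unlist(ss[c("v", "m", "h", "n", "ms", "mhf", "mhs")])
  rhs <- function(t, y, parms) {
    st <- as.list(y)
    list(stellate_derivative(st, p$stellate,
                             membrane_inputs(i_ext = -2.7)))
  }
  ode <- deSolve::rk4(y0, times = seq(0, 200, by = 0.05), func = rhs,
                      parms = NULL)
  v_ode <- ode[match(sim$traces$time, ode[, "time"]), "v"]
  expect_lt(max(abs(sim$traces$v - v_ode)), 0.1)
})

test_that("raster text round trip preserves the spike table", {
  sim <- integrate_network(build_motif(), stimulus_program(noise = noise_spec()),
                           simulation_config(duration = 400), trial_seed = 3)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_raster(sim, path)
  back <- read_raster(path)
  expect_equal(back$neuron, sim$spikes$neuron)
  expect_equal(back$time, sim$spikes$time, tolerance = 1e-9)
  expect_equal(back$cell_type, sim$spikes$cell_type)
})
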