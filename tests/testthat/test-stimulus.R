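# Synapses, theta drive, pulse trains and conductance noise.

test_that("presynaptic activation is the documented sigmoid", {
  expect_equal(presynaptic_activation(0), 0.5)
  expect_equal(presynaptic_activation(4), (1 + tanh(1)) / 2)
  expect_equal(presynaptic_activation(-4), (1 - tanh(1)) / 2)
  v <- seq(-80, 40, by = 1)
  f <- presynaptic_activation(v)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  # strictly increasing away from the saturated tails
  expect_true(all(diff(presynaptic_activation(seq(-12, 12, 0.5))) > 0))
  expect_error(presynaptic_activation(NaN), "finite")
})

test_that("synapse defaults carry the published constants", {
  e <- synapse_params("excitatory")
  i <- synapse_params("inhibitory")
  expect_equal(c(e$g_max, e$e_rev, e$alpha_s, e$beta_s), c(0.03, 0, 100, 0.33))
  expect_equal(c(i$g_max, i$e_rev, i$alpha_s, i$beta_s), c(1, -80, 3.33, 0.11))
})

test_that("synaptic gate dynamics have the analytic fixed point", {
  p <- synapse_params("inhibitory")
  v_pre <- 10
  f <- presynaptic_activation(v_pre)
  s_star <- f * p$alpha_s / (f * p$alpha_s + p$beta_s)
  expect_equal(synapse_gate_derivative(s_star, v_pre, p), 0, tolerance = 1e-12)
  # fully open gate with silent presynaptic cell decays at rate beta
  expect_equal(synapse_gate_derivative(1, -100, p),
               presynaptic_activation(-100) * p$alpha_s * 0 - p$beta_s,
               tolerance = 1e-10)
  expect_error(synapse_gate_derivative(1.5, 0, p), "\\[0, 1\\]")
})

test_that("synaptic current is conductance times driving force", {
  p <- synapse_params("inhibitory")
  expect_equal(synaptic_current(0.5, -60, p, g = 0.6), 0.6 * 0.5 * 20)
  expect_equal(synaptic_current(0.5, -80, p, g = 0.6), 0)  # at reversal
  pe <- synapse_params("excitatory")
  expect_lt(synaptic_current(0.5, -60, pe), 0)  # excitatory inward below 0 mV
})

test_that("theta drive has the documented zeros, extrema and period", {
  d <- theta_drive(amplitude = 0.04, freq = 8, phase = 0)
  expect_equal(theta_current(0, -65, d), 0)
  # quarter period of 8 Hz = 31.25 ms: sin = 1
  expect_equal(theta_current(31.25, -65, d), 0.04 * 15)
  expect_equal(theta_current(31.25, -80, d), 0)  # at the threshold voltage
  tt <- seq(0, 125, by = 0.5)
  expect_equal(theta_current(tt, -65, d), theta_current(tt + 125, -65, d),
               tolerance = 1e-9)
  expect_error(theta_current(-1, -65, d), "non-negative")
})

test_that("swept theta phase is continuous with the correct instantaneous frequency", {
  d <- theta_drive(phase = pi, sweep = list(f_min = 6, f_max = 12,
                                            period = 2000))
  expect_equal(theta_phase(0, d), pi)
  # numerical phase derivative equals 2*pi*f_inst/1000
  h <- 1e-4
  f_inst <- function(t) (theta_phase(t + h, d) - theta_phase(t - h, d)) /
    (2 * h) * 1000 / (2 * pi)
  expect_equal(f_inst(0), 9, tolerance = 1e-6)      # mid frequency at t = 0
  expect_equal(f_inst(500), 12, tolerance = 1e-6)   # fastest at quarter period
  expect_equal(f_inst(1500), 6, tolerance = 1e-6)   # slowest at three quarters
  # phase over one sweep period advances by the mid-frequency cycle count
  expect_equal(theta_phase(2000, d) - theta_phase(0, d), 2 * pi * 9 * 2,
               tolerance = 1e-9)
})

test_that("pulse schedule arithmetic matches the onset formula", {
  spec <- pulse_train(T = 125, n = 40)
  expect_equal(spec$lambda, 5000)  # revisit interval defaults to n*T
  sch <- pulse_schedule(i = c(0, 1, 2), k = c(0, 1), spec)
  expect_equal(sort(sch$onset), sort(c(0, 125, 250, 5000, 5125, 5250)))
  expect_true(all(sch$offset - sch$onset == 40))
  off <- pulse_schedule(2, 0, pulse_train(T = 125, t0 = 100))
  expect_equal(off$onset, 350)
  expect_error(pulse_schedule(-1), ">= 0")
})

test_that("pulse waveform has the documented baseline, rise and continuity", {
  spec <- pulse_train()
  on <- 100
  # baseline before the first onset; zero current when never pulsed
  expect_equal(pulse_current(50, on, spec), -0.05)
  expect_equal(pulse_current(c(10, 500), numeric(0), spec), c(0, 0))
  # rises from p_low toward p_high with tau_r = 1 ms
  expect_equal(pulse_current(on, on, spec), -0.05, tolerance = 1e-12)
  expect_equal(pulse_current(on + 1, on, spec),
               1 + (-0.05 - 1) * exp(-1), tolerance = 1e-12)
  expect_equal(pulse_current(on + 39.9, on, spec), 1, tolerance = 1e-10)
  # continuous at the off-switch, then decays toward baseline with tau_f
  left <- pulse_current(on + 40 - 1e-9, on, spec)
  right <- pulse_current(on + 40 + 1e-9, on, spec)
  expect_equal(left, right, tolerance = 1e-6)
  expect_equal(pulse_current(on + 300, on, spec), -0.05, tolerance = 1e-10)
  # time translation invariance
  tt <- seq(0, 400, by = 0.7)
  expect_equal(pulse_current(tt + 37, on + 37, spec),
               pulse_current(tt, on, spec))
})

test_that("conductance noise has the documented scale and determinism", {
  spec <- noise_spec()
  x <- noise_current(20000, -70, spec, seed = 7)
  y <- noise_current(20000, -70, spec, seed = 7)
  expect_identical(x, y)
  u <- x / (spec$g_amp * (-70 - spec$e_rev))
  expect_true(all(u >= -1 & u <= 1))
  expect_equal(mean(u), 0, tolerance = 0.02)
  expect_equal(mean(abs(u)), 0.5, tolerance = 0.02)
  # mean |I| at a -70 mV holding potential is ~10% of the pulse amplitude
  expect_equal(mean(abs(x)), 0.1, tolerance = 0.01)
  expect_equal(noise_current(5, -65, spec, 1), rep(0, 5))  # at the reversal
  expect_equal(noise_current(5, -70, noise_spec(g_amp = 0), 1), rep(0, 5))
})
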