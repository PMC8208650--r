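# Gating kinetics and single-cell current-balance equations.

vgrid <- seq(-120, 60, by = 0.5)

test_that("removable singularities of the rate functions evaluate to their limits", {
  # stellate alpha_m at v = -23: x/(e^x - 1) -> 1 as x -> 0
  rs <- gating_rates(-23, "stellate")
  expect_equal(rs$alpha[rs$gate == "m"], 1)
  # stellate alpha_n at v = -27: 0.1 * limit
  rn <- gating_rates(-27, "stellate")
  expect_equal(rn$alpha[rn$gate == "n"], 0.1)
  # interneuron alpha_m at v = -35, alpha_n at v = -34
  ri <- gating_rates(-35, "interneuron")
  expect_equal(ri$alpha[ri$gate == "m"], 1)
  rin <- gating_rates(-34, "interneuron")
  expect_equal(rin$alpha[rin$gate == "n"], 0.1)
  # continuity across the singularity
  eps <- 1e-9
  lo <- gating_rates(-23 - eps, "stellate")$alpha[1]
  hi <- gating_rates(-23 + eps, "stellate")$alpha[1]
  expect_equal(lo, hi, tolerance = 1e-6)
})

test_that("rate functions hit their closed-form anchor points", {
  rs <- gating_rates(c(-37, -48), "stellate")
  # alpha_h(-37) = 0.07 e^0; beta_m(-48) = 4 e^0
  expect_equal(rs$alpha[rs$gate == "h" & rs$v == -37], 0.07)
  expect_equal(rs$beta[rs$gate == "m" & rs$v == -48], 4)
  expect_equal(rs$beta[rs$gate == "n" & rs$v == -37], 0.125)
  ri <- gating_rates(c(-58, -44, -60, -28), "interneuron")
  expect_equal(ri$alpha[ri$gate == "h" & ri$v == -58], 0.07)
  expect_equal(ri$beta[ri$gate == "n" & ri$v == -44], 0.125)
  expect_equal(ri$beta[ri$gate == "m" & ri$v == -60], 4)
  expect_equal(ri$beta[ri$gate == "h" & ri$v == -28], 0.5)
})

test_that("sodium inactivation rates have the correct monotonicity", {
  for (cell in c("stellate", "interneuron")) {
    r <- gating_rates(vgrid, cell)
    ah <- r$alpha[r$gate == "h"]
    bh <- r$beta[r$gate == "h"]
    expect_true(all(diff(ah) < 0))  # forward rate falls with depolarization
    expect_true(all(diff(bh) > 0))  # backward rate rises
  }
})

test_that("steady states lie in [0,1] and time constants are positive", {
  for (cell in c("stellate", "interneuron")) {
    k <- gating_kinetics(vgrid, cell)
    expect_true(all(k$inf >= 0 & k$inf <= 1))
    expect_true(all(k$tau > 0))
    expect_true(all(is.finite(k$inf)), info = cell)
    expect_true(all(is.finite(k$tau)), info = cell)
  }
})

test_that("directly specified stellate gates match their anchor points", {
  k <- gating_kinetics(c(-38, -79.2, -2.83), "stellate")
  pick <- function(g, v) k$inf[k$gate == g & k$v == v]
  expect_equal(pick("ms", -38), 0.5)        # half-activation of NaP
  expect_equal(pick("mhf", -79.2), 0.5)     # half-activation of fast h gate
  expect_equal(pick("mhs", -2.83), 2^-58)   # slow h gate: (1+e^0)^-58
  expect_equal(k$tau[k$gate == "ms"], rep(0.15, 3))
})

test_that("slow h gate activates at hyperpolarized potentials", {
  k <- gating_kinetics(c(-100, -73, -40), "stellate")
  mhs <- k$inf[k$gate == "mhs"]
  expect_gt(mhs[1], 0.8)
  # half-activation near -73 mV
  expect_equal(mhs[2], 0.5, tolerance = 0.05)
  expect_lt(mhs[3], 0.01)
})

test_that("interneuron phi divides the h and n time constants only", {
  k1 <- gating_kinetics(-60, "interneuron", phi = 1)
  k5 <- gating_kinetics(-60, "interneuron", phi = 5)
  expect_equal(k5$tau[k5$gate == "h"], k1$tau[k1$gate == "h"] / 5)
  expect_equal(k5$tau[k5$gate == "n"], k1$tau[k1$gate == "n"] / 5)
  expect_equal(k5$tau[k5$gate == "m"], k1$tau[k1$gate == "m"])
  expect_equal(k5$inf, k1$inf)  # steady states unaffected
})

test_that("steady_state returns one entry per gate within bounds", {
  ss <- steady_state(-65, "stellate")
  expect_named(ss, c("v", "m", "h", "n", "ms", "mhf", "mhs"),
               ignore.order = TRUE)
  expect_true(all(unlist(ss[-1]) >= 0 & unlist(ss[-1]) <= 1))
  si <- steady_state(-65, "interneuron")
  expect_named(si, c("v", "m", "h", "n"), ignore.order = TRUE)
})

test_that("stellate derivative matches an independent term-by-term oracle", {
  st <- list(v = -55, m = 0.1, h = 0.6, n = 0.2, ms = 0.3, mhf = 0.4,
             mhs = 0.2)
  p <- stellate_params()
  inp <- membrane_inputs(i_ext = 1, i_syn = 0.5, i_noise = 0.2)
  d <- stellate_derivative(st, p, inp)
  v <- st$v
  # independent restatement of each membrane current
  i_na <- 52 * st$m^3 * st$h * (v - 55)
  i_k <- 11 * st$n^4 * (v + 90)
  i_l <- 0.5 * (v + 65)
  i_h <- 1.5 * (0.65 * st$mhf + 0.35 * st$mhs) * (v + 20)
  i_nap <- 0.5 * st$ms * (v - 55)
  dv <- (1 - i_na - i_k - i_l - i_h - i_nap - 0.5 - 0.2) / 1.5
  expect_equal(unname(d["v"]), dv, tolerance = 1e-12)
  # gate equations written out from the published rate functions
  x <- -0.1 * (v + 23); am <- x / expm1(x); bm <- 4 * exp(-(v + 48) / 18)
  expect_equal(unname(d["m"]), am * (1 - st$m) - bm * st$m, tolerance = 1e-10)
  ah <- 0.07 * exp(-(v + 37) / 20); bh <- 1 / (exp(-0.1 * (v + 7)) + 1)
  expect_equal(unname(d["h"]), ah * (1 - st$h) - bh * st$h, tolerance = 1e-10)
  xn <- -0.1 * (v + 27); an <- 0.1 * xn / expm1(xn)
  bn <- 0.125 * exp(-(v + 37) / 80)
  expect_equal(unname(d["n"]), an * (1 - st$n) - bn * st$n, tolerance = 1e-10)
  ms_inf <- 1 / (1 + exp(-(v + 38) / 6.5))
  expect_equal(unname(d["ms"]), (ms_inf - st$ms) / 0.15, tolerance = 1e-10)
})

test_that("interneuron derivative matches an independent oracle with instantaneous m", {
  st <- list(v = -50, h = 0.5, n = 0.3)
  p <- interneuron_params()
  inp <- membrane_inputs(i_ext = 0.2, i_pulse = 1, i_syn = 0.3,
                         i_theta = 0.1)
  d <- interneuron_derivative(st, p, inp)
  v <- st$v
  xm <- -(v + 35) / 10
  am <- xm / expm1(xm); bm <- 4 * exp(-(v + 60) / 18)
  m <- am / (am + bm)
  i_na <- 35 * m^3 * st$h * (v - 55)
  i_k <- 9 * st$n^4 * (v + 90)
  i_l <- 0.1 * (v + 65)
  dv <- (0.2 + 1 - i_na - i_k - i_l - 0.3 - 0 - 0.1) / 1
  expect_equal(unname(d["v"]), dv, tolerance = 1e-10)
  ah <- 0.07 * exp(-(v + 58) / 20); bh <- 1 / (exp(-0.1 * (v + 28)) + 1)
  expect_equal(unname(d["h"]), 5 * (ah * (1 - st$h) - bh * st$h),
               tolerance = 1e-10)
})

test_that("derivatives vanish at equilibrium of the reduced passive cell", {
  # with all active conductances removed, e_leak is a fixed point
  p <- stellate_params(g_na = 0, g_k = 0, g_nap = 0, g_h = 0)
  st <- steady_state(-65, "stellate")
  d <- stellate_derivative(st, p, membrane_inputs())
  expect_equal(unname(d["v"]), 0, tolerance = 1e-12)
  expect_equal(unname(d[c("m", "h", "n", "ms", "mhf", "mhs")]),
               rep(0, 6), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sodium current vanishes at the sodium reversal potential", {
  st <- steady_state(55, "stellate")
  p0 <- stellate_params(g_k = 0, g_nap = 0, g_h = 0, g_leak = 0)
  d <- stellate_derivative(st, p0, membrane_inputs())
  expect_equal(unname(d["v"]), 0, tolerance = 1e-12)
})

test_that("input and gate validation rejects out-of-domain values", {
  st <- steady_state(-65, "stellate")
  expect_error(stellate_derivative(st, inputs = membrane_inputs(i_pulse = 1)),
               "stellate")
  expect_error(stellate_derivative(st, inputs = membrane_inputs(i_theta = 1)),
               "stellate")
  bad <- st; bad$m <- 1.2
  expect_error(stellate_derivative(bad), "\\[0, 1\\]")
  expect_error(membrane_inputs(i_ext = NA), "finite")
  expect_error(gating_rates(Inf, "stellate"), "finite")
  expect_error(stellate_params(h_frac_fast = 0.5, h_frac_slow = 0.4),
               "equal 1")
})
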