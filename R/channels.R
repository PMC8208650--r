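#' Stellate cell membrane parameters
#'
#' Default parameters for the single-compartment stellate cell model: fast
#' transient sodium, delayed-rectifier potassium, persistent sodium, a
#' two-component (fast/slow) h-current and leak. Conductances are in
#' mS/cm\eqn{^2}, reversal potentials in mV, capacitance in \eqn{\mu}F/cm\eqn{^2}.
#'
#' The leak conductance, leak reversal and capacitance are not constrained by
#' the channel kinetics and default to the values of the source stellate model
#' (`g_leak = 0.5`, `e_leak = -65`, `c_m = 1.5`). The h-current splits into a
#' fast and a slow gate with fixed mixing weights 0.65/0.35.
#'
#' @param c_m Specific membrane capacitance.
#' @param g_na,g_k,g_nap,g_h,g_leak Maximal conductances.
#' @param e_na,e_k,e_h,e_leak Reversal potentials.
#' @param tau_ms Persistent-sodium activation time constant (ms).
#' @param h_frac_fast,h_frac_slow h-current mixing weights; must sum to 1.
#' @return A named list of class `stellate_params`.
#' @export
stellate_params <- function(c_m = 1.5, g_na = 52, g_k = 11, g_nap = 0.5,
                            g_h = 1.5, g_leak = 0.5,
                            e_na = 55, e_k = -90, e_h = -20, e_leak = -65,
                            tau_ms = 0.15,
                            h_frac_fast = 0.65, h_frac_slow = 0.35) {
  stopifnot(c_m > 0, g_na >= 0, g_k >= 0, g_nap >= 0, g_h >= 0, g_leak >= 0,
            tau_ms > 0)
  if (abs(h_frac_fast + h_frac_slow - 1) > 1e-10)
    stop("h_frac_fast + h_frac_slow must equal 1", call. = FALSE)
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_nap = g_nap, g_h = g_h,
                 g_leak = g_leak, e_na = e_na, e_k = e_k, e_h = e_h,
                 e_leak = e_leak, tau_ms = tau_ms,
                 h_frac_fast = h_frac_fast, h_frac_slow = h_frac_slow),
            class = "stellate_params")
}

#' Fast-spiking interneuron membrane parameters
#'
#' Defaults follow the fast-spiking interneuron model with sodium and
#' potassium kinetics sped up by a temperature-like factor `phi` applied to
#' the inactivation (h) and activation (n) gates, which is what lets the cell
#' sustain high firing rates.
#'
#' @param c_m Specific membrane capacitance (\eqn{\mu}F/cm\eqn{^2}).
#' @param g_na,g_k,g_leak Maximal conductances (mS/cm\eqn{^2}).
#' @param e_na,e_k,e_leak Reversal potentials (mV).
#' @param phi Kinetic scaling of the h and n gates.
#' @return A named list of class `interneuron_params`.
#' @export
interneuron_params <- function(c_m = 1, g_na = 35, g_k = 9, g_leak = 0.1,
                               e_na = 55, e_k = -90, e_leak = -65, phi = 5) {
  stopifnot(c_m > 0, g_na >= 0, g_k >= 0, g_leak >= 0, phi > 0)
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak, phi = phi),
            class = "interneuron_params")
}

# x / (exp(x) - 1) with the removable singularity at x = 0 evaluated by its
# series limit; vectorized.
vtrap <- function(x) {
  out <- x / expm1(x)
  small <- abs(x) < 1e-7
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  out
}

#' Voltage-dependent rate functions (alpha/beta form)
#'
#' Forward and backward rates for the gates that are specified as
#' \eqn{\alpha/\beta} pairs (m, h, n). Removable singularities in the
#' \eqn{\alpha_m}/\eqn{\alpha_n} forms are evaluated by their analytic limits.
#' Rates are returned unscaled (the interneuron `phi` factor multiplies the
#' whole kinetic equation, not the rates).
#'
#' @param v Membrane potential(s), mV. Must be finite.
#' @param cell `"stellate"` or `"interneuron"`.
#' @return A tibble with columns `v`, `gate`, `alpha`, `beta`.
#' @export
gating_rates <- function(v, cell = c("stellate", "interneuron")) {
  cell <- match.arg(cell)
  if (!all(is.finite(v))) stop("v must be finite", call. = FALSE)
  if (cell == "stellate") {
    tab <- list(
      m = list(a = vtrap(-0.1 * (v + 23)), b = 4 * exp(-(v + 48) / 18)),
      h = list(a = 0.07 * exp(-(v + 37) / 20),
               b = 1 / (exp(-0.1 * (v + 7)) + 1)),
      n = list(a = 0.1 * vtrap(-0.1 * (v + 27)),
               b = 0.125 * exp(-(v + 37) / 80)))
  } else {
    tab <- list(
      m = list(a = vtrap(-(v + 35) / 10), b = 4 * exp(-(v + 60) / 18)),
      h = list(a = 0.07 * exp(-(v + 58) / 20),
               b = 1 / (exp(-0.1 * (v + 28)) + 1)),
      n = list(a = 0.1 * vtrap(-0.1 * (v + 34)),
               b = 0.125 * exp(-(v + 44) / 80)))
  }
  purrr::imap(tab, function(ab, g)
    tibble::tibble(v = v, gate = g, alpha = ab$a, beta = ab$b)) |>
    purrr::list_rbind()
}

#' Gating kinetics as (steady state, time constant) pairs
#'
#' Converts every gate of the requested cell type to the
#' \eqn{(m_\infty, \tau)} representation: \eqn{m_\infty = \alpha/(\alpha+\beta)},
#' \eqn{\tau = 1/(\alpha+\beta)} for alpha/beta gates; the persistent-sodium
#' and h-current gates are specified directly in this form. For the
#' interneuron, `phi` divides the h and n time constants.
#'
#' @inheritParams gating_rates
#' @param phi Interneuron kinetic scaling (ignored for stellate cells).
#' @return A tibble with columns `v`, `gate`, `inf`, `tau`. Stellate gates:
#'   `m`, `h`, `n`, `ms`, `mhf`, `mhs`; interneuron gates: `m`, `h`, `n`.
#' @export
gating_kinetics <- function(v, cell = c("stellate", "interneuron"), phi = 5) {
  cell <- match.arg(cell)
  rates <- gating_rates(v, cell)
  out <- dplyr::mutate(rates,
                       inf = .data$alpha / (.data$alpha + .data$beta),
                       tau = 1 / (.data$alpha + .data$beta))
  out <- dplyr::select(out, "v", "gate", "inf", "tau")
  if (cell == "interneuron") {
    out$tau <- ifelse(out$gate %in% c("h", "n"), out$tau / phi, out$tau)
    return(out)
  }
  slow_inf <- c(1 / (1 + exp(-(v + 38) / 6.5)),
                1 / (1 + exp((v + 79.2) / 9.78)),
                (1 + exp((v + 2.83) / 15.9))^(-58))
  slow_tau <- c(rep(0.15, length(v)),
                0.51 / (exp((v - 1.7) / 10) + exp(-(v + 340) / 52)) + 1,
                5.6 / (exp((v - 1.7) / 14) + exp(-(v + 260) / 43)) + 1)
  slow_gate <- rep(c("ms", "mhf", "mhs"), each = length(v))
  slow <- tibble::tibble(v = rep(v, 3), gate = slow_gate,
                         inf = slow_inf, tau = slow_tau)
  dplyr::bind_rows(out, slow)
}

#' Steady gating state at a holding potential
#'
#' All gates set to their voltage-dependent steady state at `v`; used for
#' initial conditions.
#'
#' @param v Holding potential (scalar, mV).
#' @param cell Cell type.
#' @return Named list: `v` plus one entry per gate.
#' @export
steady_state <- function(v, cell = c("stellate", "interneuron")) {
  cell <- match.arg(cell)
  k <- gating_kinetics(v, cell)
  out <- as.list(stats::setNames(k$inf, k$gate))
  c(list(v = v), out)
}

#' Membrane inputs
#'
#' Container for the input currents entering a cell's current-balance
#' equation (all \eqn{\mu}A/cm\eqn{^2}). Pulse and theta terms apply only to
#' interneurons.
#'
#' @param i_ext Constant external current.
#' @param i_pulse Transient pulse current (interneurons only).
#' @param i_syn Summed synaptic current.
#' @param i_noise Conductance-noise current.
#' @param i_theta Theta-drive current (interneurons only).
#' @return Named list of class `membrane_inputs`.
#' @export
membrane_inputs <- function(i_ext = 0, i_pulse = 0, i_syn = 0, i_noise = 0,
                            i_theta = 0) {
  vals <- c(i_ext, i_pulse, i_syn, i_noise, i_theta)
  if (!all(is.finite(vals))) stop("inputs must be finite", call. = FALSE)
  structure(list(i_ext = i_ext, i_pulse = i_pulse, i_syn = i_syn,
                 i_noise = i_noise, i_theta = i_theta),
            class = "membrane_inputs")
}

check_gates <- function(state, gates) {
  g <- unlist(state[gates])
  if (any(g < 0 | g > 1)) stop("gate values must lie in [0, 1]", call. = FALSE)
  if (!is.finite(state$v)) stop("v must be finite", call. = FALSE)
}

#' Stellate membrane derivative
#'
#' Time derivatives of the stellate state under the current-balance equation
#' \deqn{C \dot V = I_{ext} - I_{Na} - I_K - I_L - I_h - I_{NaP} - I_{syn} - I_{noise},}
#' with \eqn{I_h = g_h (0.65\, m_{hf} + 0.35\, m_{hs}) (V - E_h)} and
#' first-order gate kinetics. Pulse and theta inputs must be zero (they do not
#' enter the stellate equation).
#'
#' @param state Named list with `v`, `m`, `h`, `n`, `ms`, `mhf`, `mhs`.
#' @param params A [stellate_params()] object.
#' @param inputs A [membrane_inputs()] object.
#' @return Named numeric vector of derivatives (`v` in mV/ms, gates in 1/ms).
#' @export
stellate_derivative <- function(state, params = stellate_params(),
                                inputs = membrane_inputs()) {
  check_gates(state, c("m", "h", "n", "ms", "mhf", "mhs"))
  if (inputs$i_pulse != 0 || inputs$i_theta != 0)
    stop("pulse and theta inputs do not enter the stellate equation",
         call. = FALSE)
  v <- state$v
  k <- gating_kinetics(v, "stellate")
  kv <- split(k[, c("inf", "tau")], k$gate)
  i_na <- params$g_na * state$m^3 * state$h * (v - params$e_na)
  i_k <- params$g_k * state$n^4 * (v - params$e_k)
  i_l <- params$g_leak * (v - params$e_leak)
  i_h <- params$g_h * (params$h_frac_fast * state$mhf +
                         params$h_frac_slow * state$mhs) * (v - params$e_h)
  i_nap <- params$g_nap * state$ms * (v - params$e_na)
  dv <- (inputs$i_ext - i_na - i_k - i_l - i_h - i_nap - inputs$i_syn -
           inputs$i_noise) / params$c_m
  d <- function(g) (kv[[g]]$inf - state[[g]]) / kv[[g]]$tau
  c(v = dv, m = d("m"), h = d("h"), n = d("n"), ms = d("ms"),
    mhf = d("mhf"), mhs = d("mhs"))
}

#' Interneuron membrane derivative
#'
#' Time derivatives of the interneuron state under
#' \deqn{C \dot V = I_{ext} + I_{pulse} - I_{Na} - I_K - I_L - I_{syn} - I_{noise} - I_\theta,}
#' with the theta drive entering with a minus sign (a positive theta current
#' hyperpolarizes). The h and n kinetics are scaled by `phi`; the fast Na
#' activation gate is instantaneous, \eqn{m = m_\infty(v)}, as in the source
#' fast-spiking model (a dynamic m with unscaled kinetics cannot support
#' high-frequency firing).
#'
#' @param state Named list with `v`, `h`, `n`.
#' @param params An [interneuron_params()] object.
#' @param inputs A [membrane_inputs()] object.
#' @return Named numeric vector of derivatives.
#' @export
interneuron_derivative <- function(state, params = interneuron_params(),
                                   inputs = membrane_inputs()) {
  check_gates(state, c("h", "n"))
  v <- state$v
  k <- gating_kinetics(v, "interneuron", phi = params$phi)
  kv <- split(k[, c("inf", "tau")], k$gate)
  m <- kv$m$inf
  i_na <- params$g_na * m^3 * state$h * (v - params$e_na)
  i_k <- params$g_k * state$n^4 * (v - params$e_k)
  i_l <- params$g_leak * (v - params$e_leak)
  dv <- (inputs$i_ext + inputs$i_pulse - i_na - i_k - i_l - inputs$i_syn -
           inputs$i_noise - inputs$i_theta) / params$c_m
  d <- function(g) (kv[[g]]$inf - state[[g]]) / kv[[g]]$tau
  c(v = dv, h = d("h"), n = d("n"))
}
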