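#' Synapse parameters
#'
#' First-order kinetic synapse \eqn{\dot s = F(v_{pre})\alpha_s(1-s) - \beta_s s}
#' with conductance current \eqn{I_{syn} = g\, s\, (v_{post} - E_{syn})}.
#' Rates are in 1/ms: the published rate constants (e.g. excitatory forward
#' rate 100, inhibitory 3.33) are only consistent with millisecond-scale
#' synaptic dynamics on that scale, so they are interpreted as ms\eqn{^{-1}}.
#'
#' @param type `"excitatory"` (reversal 0 mV) or `"inhibitory"` (-80 mV).
#' @param g_max Maximal conductance (mS/cm\eqn{^2}); connection weights scale it.
#' @param e_rev Reversal potential (mV).
#' @param alpha_s,beta_s Forward/reverse rates (1/ms).
#' @return Named list of class `synapse_params`.
#' @export
synapse_params <- function(type = c("excitatory", "inhibitory"),
                           g_max = NULL, e_rev = NULL,
                           alpha_s = NULL, beta_s = NULL) {
  type <- match.arg(type)
  def <- if (type == "excitatory")
    list(g_max = 0.03, e_rev = 0, alpha_s = 100, beta_s = 0.33)
  else
    list(g_max = 1.0, e_rev = -80, alpha_s = 3.33, beta_s = 0.11)
  out <- list(type = type,
              g_max = g_max %||% def$g_max,
              e_rev = e_rev %||% def$e_rev,
              alpha_s = alpha_s %||% def$alpha_s,
              beta_s = beta_s %||% def$beta_s)
  stopifnot(out$g_max >= 0, out$alpha_s >= 0, out$beta_s >= 0)
  structure(out, class = "synapse_params")
}

#' Presynaptic activation function
#'
#' Sigmoidal transfer \eqn{F(v) = (1 + \tanh(v/4))/2} mapping presynaptic
#' voltage to the synaptic opening drive; close to 0 at rest and close to 1
#' during an action potential.
#'
#' @param v_pre Presynaptic membrane potential(s), mV.
#' @return Activation in (0, 1), same length as `v_pre`.
#' @export
presynaptic_activation <- function(v_pre) {
  if (!all(is.finite(v_pre))) stop("v_pre must be finite", call. = FALSE)
  (1 + tanh(v_pre / 4)) / 2
}

#' Synaptic gate derivative
#'
#' @param s Gate value(s) in \[0, 1\].
#' @param v_pre Presynaptic voltage (mV).
#' @param params A [synapse_params()] object.
#' @return ds/dt (1/ms).
#' @export
synapse_gate_derivative <- function(s, v_pre, params = synapse_params("inhibitory")) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]", call. = FALSE)
  presynaptic_activation(v_pre) * params$alpha_s * (1 - s) - params$beta_s * s
}

#' Synaptic current
#'
#' @param s Gate value(s) in \[0, 1\].
#' @param v_post Postsynaptic voltage (mV).
#' @param params A [synapse_params()] object.
#' @param g Conductance (mS/cm\eqn{^2}); defaults to `params$g_max`.
#' @return Current (\eqn{\mu}A/cm\eqn{^2}); positive for outward driving force.
#' @export
synaptic_current <- function(s, v_post, params = synapse_params("inhibitory"),
                             g = params$g_max) {
  if (any(s < 0 | s > 1)) stop("s must lie in [0, 1]", call. = FALSE)
  g * s * (v_post - params$e_rev)
}

#' Theta-drive specification
#'
#' Sinusoidal conductance drive onto interneurons,
#' \eqn{I_\theta = A \sin(2\pi\omega t + \phi)(V - V_{th})}, entering the
#' interneuron equation with a minus sign: the positive half of the sinusoid
#' hyperpolarizes, the negative half is the depolarized ("receptive") window.
#' A swept-frequency drive replaces \eqn{2\pi\omega t} by the accumulated
#' phase of a sinusoidally modulated instantaneous frequency (phase
#' continuous).
#'
#' @param amplitude Drive conductance amplitude A (mS/cm\eqn{^2}).
#' @param freq Frequency \eqn{\omega} (Hz); ignored when `sweep` is given.
#' @param phase Phase offset \eqn{\phi} (rad).
#' @param v_th Threshold voltage (mV).
#' @param sweep Optional `list(f_min, f_max, period)`: instantaneous frequency
#'   oscillates sinusoidally between `f_min` and `f_max` Hz with the given
#'   period (ms).
#' @return Named list of class `theta_drive`.
#' @export
theta_drive <- function(amplitude = 0.04, freq = 8, phase = 0, v_th = -80,
                        sweep = NULL) {
  stopifnot(amplitude >= 0)
  if (!is.null(sweep)) {
    stopifnot(sweep$f_min > 0, sweep$f_max >= sweep$f_min, sweep$period > 0)
  } else {
    stopifnot(freq > 0)
  }
  structure(list(amplitude = amplitude, freq = freq, phase = phase,
                 v_th = v_th, sweep = sweep),
            class = "theta_drive")
}

#' Accumulated theta phase
#'
#' Phase of the drive sinusoid at time `t` (rad, unwrapped). For a fixed
#' frequency this is \eqn{2\pi\omega t/1000 + \phi}; for a swept drive it is
#' the integral of the instantaneous frequency.
#'
#' @param t Time(s), ms.
#' @param drive A [theta_drive()] object.
#' @return Unwrapped phase(s) in radians.
#' @export
theta_phase <- function(t, drive = theta_drive()) {
  if (is.null(drive$sweep))
    return(drive$phase + 2 * pi * drive$freq * t / 1000)
  f_mid <- (drive$sweep$f_min + drive$sweep$f_max) / 2
  f_half <- (drive$sweep$f_max - drive$sweep$f_min) / 2
  P <- drive$sweep$period
  drive$phase + (2 * pi / 1000) *
    (f_mid * t + f_half * (P / (2 * pi)) * (1 - cos(2 * pi * t / P)))
}

#' Theta-drive current
#'
#' @param t Time(s), ms (non-negative).
#' @param v Membrane potential (mV).
#' @param drive A [theta_drive()] object.
#' @return Current (\eqn{\mu}A/cm\eqn{^2}).
#' @export
theta_current <- function(t, v, drive = theta_drive()) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  drive$amplitude * sin(theta_phase(t, drive)) * (v - drive$v_th)
}

#' Sequential pulse-train specification
#'
#' Transient current pulses delivered to interneurons. Interneuron `i` (0-based
#' position in the input order) receives pulse onsets at
#' \eqn{t = iT + k\lambda} (k = 0, 1, ...), each of duration `p_width`. The
#' pulse rises from the baseline `p_low` toward `p_high` with time constant
#' `tau_r` and decays back with `tau_f` (continuous at the off-switch). In
#' ring runs the revisit interval is \eqn{\lambda = NT}.
#'
#' @param p_low Baseline current (\eqn{\mu}A/cm\eqn{^2}).
#' @param p_high Peak current (\eqn{\mu}A/cm\eqn{^2}).
#' @param tau_r,tau_f Rise/fall time constants (ms).
#' @param p_width Pulse duration (ms).
#' @param T Inter-neuron onset interval (ms).
#' @param lambda Revisit interval \eqn{\lambda} (ms); default `n * T`.
#' @param n Ring size (number of scheduled interneurons).
#' @param t0 Global offset added to every onset (ms).
#' @return Named list of class `pulse_train`.
#' @export
pulse_train <- function(p_low = -0.05, p_high = 1, tau_r = 1, tau_f = 2,
                        p_width = 40, T = 125, lambda = NULL, n = 1, t0 = 0) {
  stopifnot(p_width > 0, T > 0, tau_r > 0, tau_f > 0, n >= 1)
  lambda <- lambda %||% (n * T)
  stopifnot(lambda > 0)
  structure(list(p_low = p_low, p_high = p_high, tau_r = tau_r, tau_f = tau_f,
                 p_width = p_width, T = T, lambda = lambda, n = n, t0 = t0),
            class = "pulse_train")
}

#' Pulse onset/offset schedule
#'
#' Onset of the k-th pulse to neuron position `i` is `t0 + i*T + k*lambda`;
#' the offset follows after `p_width`.
#'
#' @param i Neuron position(s) in the input order (0-based, vectorized).
#' @param k Repeat index (0-based, vectorized).
#' @param spec A [pulse_train()] object.
#' @return Tibble with columns `i`, `k`, `onset`, `offset` (ms).
#' @export
pulse_schedule <- function(i, k = 0, spec = pulse_train()) {
  if (any(i < 0) || any(k < 0)) stop("i and k must be >= 0", call. = FALSE)
  d <- tidyr::expand_grid(i = as.integer(i), k = as.integer(k))
  dplyr::mutate(d,
                onset = spec$t0 + .data$i * spec$T + .data$k * spec$lambda,
                offset = .data$onset + spec$p_width) |>
    dplyr::arrange(.data$onset)
}

#' Pulse current waveform
#'
#' Evaluates the pulse current for one neuron given its sorted onset times.
#'
#' @param t Time(s), ms.
#' @param onsets Sorted pulse onset times (ms).
#' @param spec A [pulse_train()] object (shape parameters).
#' @return Current (\eqn{\mu}A/cm\eqn{^2}) at each `t`.
#' @export
pulse_current <- function(t, onsets, spec = pulse_train()) {
  onsets <- sort(onsets)
  out <- rep(spec$p_low, length(t))
  if (length(onsets) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, onsets)
  p_te <- spec$p_high + (spec$p_low - spec$p_high) * exp(-spec$p_width / spec$tau_r)
  live <- idx > 0
  ts <- onsets[pmax(idx, 1)]
  rising <- live & t < ts + spec$p_width
  falling <- live & !rising
  out[rising] <- spec$p_high + (spec$p_low - spec$p_high) *
    exp(-(t[rising] - ts[rising]) / spec$tau_r)
  out[falling] <- spec$p_low + (p_te - spec$p_low) *
    exp(-(t[falling] - (ts[falling] + spec$p_width)) / spec$tau_f)
  out
}

#' Conductance-noise specification
#'
#' Per-cell conductance noise \eqn{I_{noise} = g_{amp}\, u\, (v - E_{rev})}
#' with \eqn{u \sim U(-1, 1)} redrawn every integration step (the resample
#' interval equals the step). The default amplitude makes the mean absolute
#' noise current on interneurons about 10% of the pulse amplitude at a
#' resting potential near -70 mV.
#'
#' @param g_amp Noise conductance scale (mS/cm\eqn{^2}).
#' @param e_rev Noise reversal potential (mV).
#' @return Named list of class `noise_spec`.
#' @export
noise_spec <- function(g_amp = 0.04, e_rev = -65) {
  stopifnot(g_amp >= 0)
  structure(list(g_amp = g_amp, e_rev = e_rev), class = "noise_spec")
}

#' Noise current sample path
#'
#' Reproduces the engine's uniform draws for testing: returns
#' \eqn{g_{amp} u_j (v - E_{rev})} for `n` consecutive draws under `seed`.
#'
#' @param n Number of draws.
#' @param v Membrane potential (mV).
#' @param spec A [noise_spec()] object.
#' @param seed Generator seed.
#' @return Numeric vector of length `n`.
#' @export
noise_current <- function(n, v, spec = noise_spec(), seed = 1) {
  u <- unif_sym_cpp(n, seed)
  spec$g_amp * u * (v - spec$e_rev)
}
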