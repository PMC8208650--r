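#' Sequential pulse stream
#'
#' Assigns a [pulse_train()] schedule to interneurons in input order: the
#' j-th cell of `order` takes position `j - 1` in the schedule, so its onsets
#' are `t0 + (j-1)*T + k*lambda`.
#'
#' @param pulse A [pulse_train()] object.
#' @param order Interneuron ids in the order the input visits them.
#' @return A stream object for [stimulus_program()].
#' @export
pulse_stream <- function(pulse, order) {
  stopifnot(inherits(pulse, "pulse_train"), length(order) >= 1)
  structure(list(kind = "sequential", pulse = pulse,
                 order = as.integer(order)), class = "pulse_stream")
}

#' Explicit pulse events
#'
#' Delivers pulses with the shape of `pulse` at explicit onset times, e.g. a
#' single toggle pulse to one interneuron.
#'
#' @param pulse A [pulse_train()] object (shape parameters; its schedule
#'   fields are ignored).
#' @param cell Target interneuron id.
#' @param onsets Onset times (ms).
#' @return A stream object for [stimulus_program()].
#' @export
pulse_events <- function(pulse, cell, onsets) {
  stopifnot(inherits(pulse, "pulse_train"), length(cell) == 1)
  structure(list(kind = "events", pulse = pulse, cell = as.integer(cell),
                 onsets = as.numeric(onsets)), class = "pulse_stream")
}

#' Stimulus program
#'
#' Bundles the external drives of a simulation: an optional theta drive (all
#' interneurons), any number of pulse streams, and conductance noise (all
#' cells).
#'
#' @param theta A [theta_drive()] or `NULL`.
#' @param streams A [pulse_stream()] / [pulse_events()] object or a list of
#'   them.
#' @param noise A [noise_spec()]; use `noise_spec(g_amp = 0)` for
#'   deterministic runs.
#' @return Named list of class `stimulus_program`.
#' @export
stimulus_program <- function(theta = NULL, streams = list(),
                             noise = noise_spec()) {
  if (inherits(streams, "pulse_stream")) streams <- list(streams)
  stopifnot(all(purrr::map_lgl(streams, inherits, "pulse_stream")))
  structure(list(theta = theta, streams = streams, noise = noise),
            class = "stimulus_program")
}

#' Simulation configuration
#'
#' @param dt Integration step (ms).
#' @param duration Simulated time (ms).
#' @param n_trials Number of trials (distinct noise/initial-condition seeds).
#' @param seed Base seed; trial `j` uses `seed + j - 1` unless `seeds` is
#'   given explicitly.
#' @param seeds Optional explicit per-trial seeds.
#' @param method `"euler"` (fixed-step forward Euler) or `"rk4"` (classical
#'   fixed-step 4th order; the reference integrator).
#' @param record Cell ids whose voltage to record, `"all"`, or `NULL`.
#' @param record_dt Trace sampling interval (ms); defaults to `dt`.
#' @param init_v Either a length-2 range for per-cell uniform initial
#'   voltages (drawn under the trial seed, gates at steady state) or a
#'   vector of fixed initial voltages, one per cell (wrap in `I()` for a
#'   two-cell network to disambiguate from a range).
#' @param spike_threshold Upward-crossing detection threshold (mV).
#' @param refractory Minimum spike separation (ms).
#' @return Named list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.01, duration = 2000, n_trials = 1,
                              seed = 1, seeds = NULL,
                              method = c("euler", "rk4"),
                              record = NULL, record_dt = NULL,
                              init_v = c(-70, -60),
                              spike_threshold = 0, refractory = 2) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > 0, n_trials >= 1)
  seeds <- seeds %||% (seed + seq_len(n_trials) - 1)
  if (anyDuplicated(seeds)) stop("trial seeds must be distinct", call. = FALSE)
  structure(list(dt = dt, duration = duration, n_trials = n_trials,
                 seeds = seeds, method = method, record = record,
                 record_dt = record_dt %||% dt, init_v = init_v,
                 spike_threshold = spike_threshold, refractory = refractory),
            class = "simulation_config")
}

# Resolve pulse streams into the per-cell onset lists the engine consumes.
resolve_pulses <- function(program, net, duration) {
  cells <- integer(0); onsets <- list()
  shape <- list(p_low = numeric(0), p_high = numeric(0), tau_r = numeric(0),
                tau_f = numeric(0), width = numeric(0))
  add <- function(cell, on, p) {
    i <- match(cell, cells)
    if (!is.na(i)) {
      onsets[[i]] <<- sort(c(onsets[[i]], on))
      return(invisible())
    }
    cells <<- c(cells, cell)
    onsets[[length(cells)]] <<- sort(on)
    shape$p_low <<- c(shape$p_low, p$p_low)
    shape$p_high <<- c(shape$p_high, p$p_high)
    shape$tau_r <<- c(shape$tau_r, p$tau_r)
    shape$tau_f <<- c(shape$tau_f, p$tau_f)
    shape$width <<- c(shape$width, p$p_width)
  }
  for (st in program$streams) {
    if (st$kind == "sequential") {
      p <- st$pulse
      for (j in seq_along(st$order)) {
        k <- 0:max(0, floor((duration - p$t0 - (j - 1) * p$T) / p$lambda))
        on <- p$t0 + (j - 1) * p$T + k * p$lambda
        on <- on[on <= duration]
        add(st$order[j], on, p)
      }
    } else {
      add(st$cell, st$onsets, st$pulse)
    }
  }
  if (length(cells) == 0) return(list())
  it <- net$cells$type[cells]
  if (any(it != "interneuron"))
    stop("pulse streams may target interneurons only", call. = FALSE)
  list(cells = as.integer(cells), onsets = onsets,
       p_low = shape$p_low, p_high = shape$p_high, tau_r = shape$tau_r,
       tau_f = shape$tau_f, width = shape$width)
}

resolve_theta <- function(theta) {
  if (is.null(theta)) return(list())
  list(amplitude = theta$amplitude, freq = theta$freq %||% 8,
       phase = theta$phase, v_th = theta$v_th, sweep = theta$sweep)
}

#' Integrate one trial of a network simulation
#'
#' Forward-Euler (or fixed-step RK4) integration of the coupled
#' stellate/interneuron network with synaptic gating, pulse, theta and noise
#' drives. Synaptic gates are integrated per presynaptic cell (one gate per
#' source, shared across its targets) and all gating variables are clamped to
#' \[0, 1\] after every step (clamp events are counted and reported). Spikes
#' are detected online as upward threshold crossings with linear
#' interpolation and a refractory window.
#'
#' @param net An `mec_network`.
#' @param program A [stimulus_program()].
#' @param config A [simulation_config()]; `n_trials` is ignored (see
#'   [run_trials()]).
#' @param trial_seed Seed for this trial's initial conditions and noise.
#' @return An object of class `mec_sim`: `spikes` (tibble: `trial`, `neuron`,
#'   `cell_type`, `time`), `traces` (tibble: `trial`, `neuron`, `time`, `v`),
#'   `clamp_count`, `final_v`, plus the inputs.
#' @export
integrate_network <- function(net, program = stimulus_program(),
                              config = simulation_config(),
                              trial_seed = config$seeds[1]) {
  stopifnot(inherits(net, "mec_network"))
  nc <- nrow(net$cells)
  type_code <- ifelse(net$cells$type == "stellate", 0L, 1L)
  se <- net$params$syn_exc; si <- net$params$syn_inh
  rec <- config$record
  rec_cells <- if (is.null(rec)) integer(0)
  else if (identical(rec, "all")) seq_len(nc)
  else as.integer(rec)
  iv <- config$init_v
  fixed <- (length(iv) == nc) && (nc != 2 || inherits(iv, "AsIs"))
  init_fixed <- if (fixed) as.numeric(iv) else numeric(0)
  init_range <- if (fixed) c(0, 0) else {
    stopifnot(length(iv) == 2)
    as.numeric(iv)
  }
  res <- run_sim_cpp(
    cell_type = type_code,
    drive = net$cells$drive,
    stellate_par = unclass(net$params$stellate),
    inter_par = unclass(net$params$interneuron),
    syn_exc = c(se$e_rev, se$alpha_s, se$beta_s),
    syn_inh = c(si$e_rev, si$alpha_s, si$beta_s),
    edge_pre = as.integer(net$edges$pre),
    edge_post = as.integer(net$edges$post),
    edge_w = net$edges$weight,
    pulse_spec = resolve_pulses(program, net, config$duration),
    theta_spec = resolve_theta(program$theta),
    noise_g = program$noise$g_amp,
    noise_erev = program$noise$e_rev,
    dt = config$dt, duration = config$duration,
    method = if (config$method == "euler") 0L else 1L,
    seed = as.double(trial_seed),
    init_v_lo = init_range[1], init_v_hi = init_range[2],
    init_v_fixed = as.numeric(init_fixed),
    record_cells = rec_cells,
    record_every = if (length(rec_cells)) config$record_dt else 0,
    spike_thresh = config$spike_threshold,
    refractory = config$refractory)
  if (res$diverged)
    stop(sprintf("numerical divergence (|v| > 200 mV) at t = %.3f ms",
                 res$t_diverged), call. = FALSE)
  spikes <- tibble::tibble(
    trial = 1L,
    neuron = as.integer(res$spike_cell),
    cell_type = net$cells$type[res$spike_cell],
    time = res$spike_time) |>
    dplyr::arrange(.data$neuron, .data$time)
  traces <- if (length(rec_cells)) {
    v <- res$trace_v
    tibble::tibble(
      trial = 1L,
      neuron = rep(rec_cells, each = length(res$trace_t)),
      time = rep(res$trace_t, length(rec_cells)),
      v = as.vector(v))
  } else {
    tibble::tibble(trial = integer(), neuron = integer(),
                   time = numeric(), v = numeric())
  }
  structure(list(spikes = spikes, traces = traces,
                 clamp_count = res$clamp_count, final_v = res$final_v,
                 network = net, program = program, config = config,
                 seeds = trial_seed),
            class = "mec_sim")
}

#' Reference integration (fixed-step 4th-order)
#'
#' Same model and arguments as [integrate_network()] but integrated with the
#' classical 4th-order Runge-Kutta scheme at a finer step; used as the
#' numerical oracle for the Euler path.
#'
#' @inheritParams integrate_network
#' @param dt_ref Reference step (ms); should be at most `config$dt / 10`.
#' @return An `mec_sim`.
#' @export
reference_integrate <- function(net, program = stimulus_program(),
                                config = simulation_config(),
                                dt_ref = config$dt / 10,
                                trial_seed = config$seeds[1]) {
  cfg <- config
  cfg$dt <- dt_ref
  cfg$method <- "rk4"
  cfg$record_dt <- max(config$record_dt, dt_ref)
  integrate_network(net, program, cfg, trial_seed = trial_seed)
}

#' Run repeated noisy trials
#'
#' Repeats [integrate_network()] under the per-trial seeds of `config`; the
#' topology and stimulus schedule are fixed, only the initial conditions and
#' the noise process are re-seeded.
#'
#' @inheritParams integrate_network
#' @return An `mec_sim` whose `spikes`/`traces` carry a `trial` column.
#' @export
run_trials <- function(net, program = stimulus_program(),
                       config = simulation_config()) {
  sims <- purrr::map(seq_len(config$n_trials), function(j) {
    s <- integrate_network(net, program, config, trial_seed = config$seeds[j])
    s$spikes$trial <- j
    s$traces$trial <- j
    s
  })
  out <- sims[[1]]
  out$spikes <- purrr::list_rbind(purrr::map(sims, "spikes"))
  out$traces <- purrr::list_rbind(purrr::map(sims, "traces"))
  out$clamp_count <- sum(purrr::map_dbl(sims, "clamp_count"))
  out$final_v <- NULL
  out$seeds <- config$seeds
  out
}

#' @export
print.mec_sim <- function(x, ...) {
  cat("<mec_sim> ", nrow(x$network$cells), " cells, ",
      length(unique(x$spikes$trial)), " trial(s), ",
      nrow(x$spikes), " spikes over ", x$config$duration, " ms\n", sep = "")
  invisible(x)
}

#' Detect spikes in a sampled voltage trace
#'
#' Upward threshold crossings with linearly interpolated crossing times;
#' crossings within the refractory window of the previous spike are
#' discarded.
#'
#' @param time Sample times (ms, uniform).
#' @param v Voltage samples (mV).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum spike separation (ms).
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(time, v, threshold = 0, refractory = 2) {
  stopifnot(length(time) == length(v))
  n <- length(v)
  if (n < 2) return(numeric(0))
  up <- which(v[-n] < threshold & v[-1] >= threshold)
  tc <- time[up] + (time[up + 1] - time[up]) *
    (threshold - v[up]) / (v[up + 1] - v[up])
  out <- numeric(0)
  last <- -Inf
  for (t in tc) {
    if (t - last > refractory) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

#' Write / read a spike raster as columnar text
#'
#' Tab-separated columns `trial`, `neuron`, `cell_type`, `spike_time_ms`.
#'
#' @param sim An `mec_sim` (or a spikes tibble with those columns).
#' @param path File path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns a
#'   tibble.
#' @export
write_raster <- function(sim, path) {
  sp <- if (inherits(sim, "mec_sim")) sim$spikes else sim
  out <- dplyr::transmute(sp, trial = .data$trial, neuron = .data$neuron,
                          cell_type = .data$cell_type,
                          spike_time_ms = .data$time)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  tibble::tibble(trial = as.integer(d$trial), neuron = as.integer(d$neuron),
                 cell_type = d$cell_type, time = d$spike_time_ms)
}

#' Spike trains from a raster
#'
#' @param sim An `mec_sim` or spikes tibble.
#' @param neuron Neuron id.
#' @param trial Trial index.
#' @return Sorted numeric vector of spike times.
#' @export
spike_train <- function(sim, neuron, trial = 1) {
  sp <- if (inherits(sim, "mec_sim")) sim$spikes else sim
  sort(sp$time[sp$neuron == neuron & sp$trial == trial])
}
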