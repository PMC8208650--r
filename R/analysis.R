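#' Spike phase relative to the theta drive
#'
#' Maps spike times to the phase of the drive sinusoid, wrapped to
#' \[0, 2\eqn{\pi}). Because the theta current enters the interneuron
#' equation with a minus sign, phases in (\eqn{\pi}, 2\eqn{\pi}) (sinusoid
#' negative) form the depolarized half-cycle and phases in (0, \eqn{\pi}) the
#' hyperpolarized half-cycle. When no theta drive is present, pass a virtual
#' drive built from the pulse cycle (frequency `1000/T`).
#'
#' @param t Spike time(s), ms.
#' @param drive A [theta_drive()] object.
#' @return Phase(s) in \[0, 2\eqn{\pi}).
#' @export
spike_phase <- function(t, drive = theta_drive()) {
  theta_phase(t, drive) %% (2 * pi)
}

circular_mean <- function(phases) {
  if (length(phases) == 0) return(NA_real_)
  Arg(mean(exp(1i * phases))) %% (2 * pi)
}

resultant_length <- function(phases) {
  if (length(phases) == 0) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Phase histogram with circular statistics
#'
#' @param phases Phases in \[0, 2\eqn{\pi}).
#' @param n_bins Number of equal-width bins (at least 4).
#' @return A tibble of class `phase_histogram` with columns `bin_center`,
#'   `count`; attributes `circ_mean` (circular mean phase) and `resultant`
#'   (mean resultant length).
#' @export
phase_histogram <- function(phases, n_bins = 16) {
  if (n_bins < 4) stop("n_bins must be >= 4", call. = FALSE)
  breaks <- seq(0, 2 * pi, length.out = n_bins + 1)
  cnt <- if (length(phases) == 0) rep(0L, n_bins)
  else as.integer(table(cut(phases %% (2 * pi), breaks,
                            include.lowest = TRUE, labels = FALSE)) |>
                    (\(tb) {
                      out <- integer(n_bins)
                      out[as.integer(names(tb))] <- as.integer(tb)
                      out
                    })())
  out <- tibble::tibble(bin_center = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                        count = cnt)
  attr(out, "circ_mean") <- circular_mean(phases)
  attr(out, "resultant") <- resultant_length(phases)
  class(out) <- c("phase_histogram", class(out))
  out
}

# Per-train context at the event grid: previous/following spikes and their
# nearest-neighbour offsets to the other train.
spike_ctx <- function(train, other, edges) {
  # edges are segment start points: tP = last spike <= edge,
  # tF = first spike strictly after the edge
  iP <- findInterval(edges, train)
  tP <- train[iP]
  tF <- train[pmin(iP + 1, length(train))]
  nearest <- function(x) {
    i <- findInterval(x, other)
    lo <- other[pmax(i, 1)]
    hi <- other[pmin(i + 1, length(other))]
    pmin(abs(x - lo), abs(x - hi))
  }
  list(tP = tP, tF = tF, dP = nearest(tP), dF = nearest(tF))
}

spike_profile_at <- function(t, ctx1, ctx2, seg) {
  # seg indexes which inter-event segment each t belongs to
  S_one <- function(ctx) {
    tP <- ctx$tP[seg]; tF <- ctx$tF[seg]
    xISI <- tF - tP
    xP <- t - tP; xF <- tF - t
    S <- (ctx$dP[seg] * xF + ctx$dF[seg] * xP) / xISI
    list(S = S, xISI = xISI)
  }
  a <- S_one(ctx1); b <- S_one(ctx2)
  mISI <- (a$xISI + b$xISI) / 2
  (a$S * b$xISI + b$S * a$xISI) / (2 * mISI^2)
}

#' Time-averaged SPIKE dissimilarity between two spike trains
#'
#' Implements the time-resolved SPIKE dissimilarity profile (piecewise from
#' the offsets between previous/following spikes of the two trains,
#' normalised by the local mean inter-spike interval) and returns its exact
#' time average over `interval`. Auxiliary spikes are placed at the interval
#' endpoints of both trains, so empty and near-empty trains are defined; a
#' pair of identical trains (including two empty trains) has distance 0. The
#' profile is piecewise linear between consecutive spikes of the merged
#' train, so the exact average is the trapezoid sum over those segments.
#'
#' @param a,b Sorted spike-time vectors (ms) within `interval`.
#' @param interval Length-2 vector `c(t0, t1)`.
#' @return Dissimilarity in \[0, 1\]; 0 iff the trains are identical.
#' @export
spike_train_distance <- function(a, b, interval) {
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  t0 <- interval[1]; t1 <- interval[2]
  a <- sort(a[a >= t0 & a <= t1]); b <- sort(b[b >= t0 & b <= t1])
  a <- unique(c(t0, a, t1)); b <- unique(c(t0, b, t1))
  edges <- sort(unique(c(a, b)))
  ns <- length(edges) - 1
  if (ns == 0) return(0)
  ctx1 <- spike_ctx(a, b, edges[-length(edges)])
  ctx2 <- spike_ctx(b, a, edges[-length(edges)])
  seg <- seq_len(ns)
  eps <- 0  # profile evaluated as one-sided limits at segment ends
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  S_lo <- spike_profile_at(lo + eps, ctx1, ctx2, seg)
  S_hi <- spike_profile_at(hi - eps, ctx1, ctx2, seg)
  sum((S_lo + S_hi) / 2 * (hi - lo)) / (t1 - t0)
}

#' SPIKE dissimilarity profile on a time grid (brute force)
#'
#' Evaluates the dissimilarity profile pointwise on an arbitrary time grid by
#' direct search for the previous/following spikes at each time. Retained as
#' the independent cross-check for [spike_train_distance()]; the grid mean
#' converges to the exact piecewise average as the grid is refined.
#'
#' @inheritParams spike_train_distance
#' @param t Time grid (within `interval`).
#' @return Tibble with columns `t`, `S`.
#' @export
spike_profile_grid <- function(a, b, interval, t) {
  t0 <- interval[1]; t1 <- interval[2]
  a <- unique(sort(c(t0, a[a >= t0 & a <= t1], t1)))
  b <- unique(sort(c(t0, b[b >= t0 & b <= t1], t1)))
  one <- function(train, other, tt) {
    iP <- pmax(findInterval(tt, train), 1)
    tP <- train[iP]
    # at an exact spike time the segment starting there is used
    tF <- train[pmin(iP + 1, length(train))]
    nearest <- function(x) {
      i <- findInterval(x, other)
      lo <- other[pmax(i, 1)]
      hi <- other[pmin(i + 1, length(other))]
      pmin(abs(x - lo), abs(x - hi))
    }
    xISI <- pmax(tF - tP, .Machine$double.eps)
    S <- (nearest(tP) * (tF - tt) + nearest(tF) * (tt - tP)) / xISI
    list(S = S, xISI = xISI)
  }
  p1 <- one(a, b, t); p2 <- one(b, a, t)
  mISI <- (p1$xISI + p2$xISI) / 2
  tibble::tibble(t = t, S = (p1$S * p2$xISI + p2$S * p1$xISI) / (2 * mISI^2))
}

#' Trial-to-trial reliability from a spike raster
#'
#' For each neuron in `subset`, the mean of [spike_train_distance()] over all
#' unordered pairs of trials: 0 for perfectly repeatable responses, larger
#' values for unreliable ones.
#'
#' @param sim An `mec_sim` (or spikes tibble) with at least 2 trials.
#' @param subset Neuron ids to evaluate (the driven subset).
#' @param interval Analysis interval `c(t0, t1)` (ms); defaults to the full
#'   simulated duration.
#' @return A tibble of class `reliability_summary` with columns `neuron`,
#'   `mean_distance`, `n_pairs`.
#' @export
reliability <- function(sim, subset, interval = NULL) {
  sp <- if (inherits(sim, "mec_sim")) sim$spikes else sim
  if (is.null(interval)) {
    if (inherits(sim, "mec_sim")) interval <- c(0, sim$config$duration)
    else stop("interval is required for a raw spikes table", call. = FALSE)
  }
  trials <- sort(unique(sp$trial))
  if (length(trials) < 2) stop("need at least 2 trials", call. = FALSE)
  pairs <- utils::combn(trials, 2)
  out <- purrr::map(subset, function(nn) {
    tr <- purrr::map(trials, function(j) sp$time[sp$neuron == nn & sp$trial == j])
    names(tr) <- as.character(trials)
    d <- purrr::map_dbl(seq_len(ncol(pairs)), function(p)
      spike_train_distance(tr[[as.character(pairs[1, p])]],
                           tr[[as.character(pairs[2, p])]], interval))
    tibble::tibble(neuron = nn, mean_distance = mean(d),
                   n_pairs = ncol(pairs))
  }) |> purrr::list_rbind()
  class(out) <- c("reliability_summary", class(out))
  out
}

#' Smoothed trial-averaged firing-rate map
#'
#' Mean spike density across trials convolved with a Gaussian window. The
#' integral of the returned rate over the duration equals the mean spike
#' count per trial (up to Gaussian mass lost at the edges).
#'
#' @param sim An `mec_sim` or spikes tibble.
#' @param neuron Neuron id.
#' @param sigma Gaussian window width (ms).
#' @param duration Total duration (ms); defaults to the simulated duration.
#' @param dt Output sampling interval (ms).
#' @return Tibble with columns `time` (ms) and `rate` (spikes/ms).
#' @export
rate_map <- function(sim, neuron, sigma = 20, duration = NULL, dt = 1) {
  stopifnot(sigma > 0)
  sp <- if (inherits(sim, "mec_sim")) sim$spikes else sim
  if (is.null(duration)) {
    if (inherits(sim, "mec_sim")) duration <- sim$config$duration
    else duration <- max(sp$time, 0)
  }
  n_trials <- max(length(unique(sp$trial)), 1)
  tt <- seq(0, duration, by = dt)
  times <- sp$time[sp$neuron == neuron]
  rate <- if (length(times) == 0) rep(0, length(tt))
  else rowSums(outer(tt, times, function(x, s) stats::dnorm(x, s, sigma))) / n_trials
  tibble::tibble(time = tt, rate = rate)
}
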