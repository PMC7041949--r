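#' Baseline-noise and rundown model for synthetic sweeps
#'
#' Emulates the two dominant nuisance processes of long outside-out patch
#' runs: Gaussian baseline noise (the recording noise floor) and a slow
#' multiplicative rundown of response amplitude across sweeps
#' (tachyphylaxis). Rundown is the phenomenon the 10% stability filter in
#' fluctuation analysis must defeat.
#'
#' @param baseline_sd baseline noise SD (pA), >= 0.
#' @param rundown_per_sweep relative amplitude loss per sweep (fraction,
#'   |value| < 0.2; 0 disables rundown).
#' @param rundown_jitter_sd SD of multiplicative jitter on the per-sweep
#'   rundown factor (fraction).
#' @return a `noise_model` object.
#' @export
noise_model <- function(baseline_sd = 0.3, rundown_per_sweep = 0,
                        rundown_jitter_sd = 0) {
  stopifnot(is_number(baseline_sd), baseline_sd >= 0,
            is_number(rundown_per_sweep), abs(rundown_per_sweep) < 0.2,
            is_number(rundown_jitter_sd), rundown_jitter_sd >= 0)
  structure(list(baseline_sd = baseline_sd,
                 rundown_per_sweep = rundown_per_sweep,
                 rundown_jitter_sd = rundown_jitter_sd),
            class = "noise_model")
}

#' Channel-ensemble specification for synthetic patches
#'
#' Either a kinetic scheme (channels gate stochastically by exact
#' event-driven simulation) or a deterministic open-probability time course
#' (channels are thinned binomially, independently per sample).
#'
#' @param scheme a `kinetic_scheme`, or `NULL` when `popen` is given.
#' @param popen deterministic open-probability samples on the output grid,
#'   or `NULL` when `scheme` is given.
#' @param n_channels channel count N >= 1.
#' @param single_channel_current single-channel current i (pA); negative
#'   for inward.
#' @param exchange_time_10_90 10-90% solution exchange time (s); 0 means
#'   ideal square steps. Physiological piezo exchange is 250-500 us.
#' @return an `ensemble_spec` object.
#' @export
ensemble_spec <- function(scheme = NULL, popen = NULL, n_channels = 100L,
                          single_channel_current = -0.6,
                          exchange_time_10_90 = 0) {
  if (is.null(scheme) == is.null(popen)) {
    stop("give exactly one of scheme or popen")
  }
  stopifnot(n_channels >= 1L,
            is_number(single_channel_current), single_channel_current != 0,
            is_number(exchange_time_10_90), exchange_time_10_90 >= 0)
  if (!is.null(popen)) {
    stopifnot(is.numeric(popen), all(popen >= 0 & popen <= 1))
  }
  structure(list(scheme = scheme, popen = popen,
                 n_channels = as.integer(n_channels),
                 single_channel_current = single_channel_current,
                 exchange_time_10_90 = exchange_time_10_90),
            class = "ensemble_spec")
}

#' Smooth a square protocol with finite solution exchange
#'
#' Replaces each instantaneous level step with an exponential relaxation
#' whose 10-90% transit time equals `exchange_time_10_90`
#' (tau_ex = exchange / ln 9), emulating piezo-driven perfusion. A zero
#' exchange time returns the ideal square stimulus bit-identically.
#'
#' @param protocol a `stimulus_protocol`.
#' @param exchange_time_10_90 10-90% exchange time (s).
#' @param time uniform sample grid (s).
#' @return stimulus samples (pH) on the grid; a warning is raised when the
#'   exchange time exceeds the shortest epoch.
#' @export
apply_solution_exchange <- function(protocol, exchange_time_10_90, time) {
  square <- protocol_to_stimulus(protocol, time)
  if (exchange_time_10_90 == 0) return(square)
  durs <- vapply(protocol$epochs, `[[`, numeric(1), "duration")
  if (length(durs) && exchange_time_10_90 > min(durs)) {
    warning("exchange time exceeds the shortest epoch; steps will not settle")
  }
  tau_ex <- exchange_time_10_90 / log(9)
  dt <- time[2L] - time[1L]
  a <- exp(-dt / tau_ex)
  out <- numeric(length(time))
  out[1L] <- square[1L]
  # first-order relaxation toward the commanded level
  for (j in 2L:length(time)) {
    out[j] <- square[j] + (out[j - 1L] - square[j]) * a
  }
  out
}

# cumulative rundown scale factors for sweeps 1..n (sweep 1 = 1)
rundown_scales <- function(noise, n_sweeps) {
  if (noise$rundown_per_sweep == 0 && noise$rundown_jitter_sd == 0) {
    return(rep(1, n_sweeps))
  }
  eps <- stats::rnorm(n_sweeps - 1L, 0, noise$rundown_jitter_sd)
  cumprod(c(1, 1 - noise$rundown_per_sweep * (1 + eps)))
}

# exact event-driven (Gillespie) simulation of the aggregated state counts
# of n iid channels; pH switches at epoch boundaries; open count sampled
# onto the grid by zero-order hold.
gillespie_open_counts <- function(scheme, protocol, n_channels, time) {
  k <- length(scheme$states)
  cond_idx <- match(scheme$conducting, scheme$states)
  p0 <- steady_state(scheme, protocol$rest_level)
  counts <- as.integer(stats::rmultinom(1L, n_channels, p0))
  # piecewise-constant level segments over the grid span
  t_end <- time[length(time)] + (time[2L] - time[1L])
  segs <- list(); cursor <- 0
  for (e in protocol$epochs) {
    if (e$start > cursor + 1e-15) {
      segs[[length(segs) + 1L]] <- list(t0 = cursor, t1 = e$start,
                                        level = protocol$rest_level)
    }
    segs[[length(segs) + 1L]] <- list(t0 = e$start,
                                      t1 = e$start + e$duration,
                                      level = e$level)
    cursor <- e$start + e$duration
  }
  if (t_end > cursor) {
    segs[[length(segs) + 1L]] <- list(t0 = cursor, t1 = t_end,
                                      level = protocol$rest_level)
  }
  n_open <- integer(length(time))
  fill_from <- 1L
  record <- function(t_now, counts) {
    # zero-order hold: grid points strictly before t_now keep prior counts
    upto <- findInterval(t_now - 1e-15, time)
    if (upto >= fill_from) {
      n_open[fill_from:upto] <<- sum(counts[cond_idx])
      fill_from <<- upto + 1L
    }
  }
  for (seg in segs) {
    Q <- scheme_Q(scheme, seg$level)
    Qoff <- Q; diag(Qoff) <- 0
    t_now <- seg$t0
    repeat {
      rates_out <- counts * -diag(Q)   # per-state aggregate exit rates
      total <- sum(rates_out)
      if (total <= 0) { t_now <- seg$t1; break }
      t_next <- t_now + stats::rexp(1L, total)
      if (t_next >= seg$t1) { t_now <- seg$t1; break }
      record(t_next, counts)
      from <- sample.int(length(counts), 1L, prob = rates_out)
      to <- sample.int(length(counts), 1L, prob = Qoff[from, ])
      counts[from] <- counts[from] - 1L
      counts[to] <- counts[to] + 1L
      t_now <- t_next
    }
    record(seg$t1, counts)
  }
  if (fill_from <= length(time)) {
    n_open[fill_from:length(time)] <- sum(counts[cond_idx])
  }
  n_open
}

#' Simulate one stochastic patch-clamp sweep
#'
#' current(t) = scale * i * (number of channels open)(t) + Gaussian baseline
#' noise. With a kinetic scheme, the channel ensemble gates by exact
#' event-driven (Gillespie) stepping with exponential waiting times, pH
#' switching at epoch boundaries and zero-order hold onto the grid; with a
#' deterministic open-probability time course, the open count is an
#' independent binomial draw per sample. Deterministic given the seed.
#'
#' @param spec an `ensemble_spec`.
#' @param protocol a `stimulus_protocol`.
#' @param noise a `noise_model`.
#' @param seed integer seed.
#' @param time uniform sample grid (s); default 10 kHz over the protocol.
#' @param meta a `recording_meta`.
#' @param sweep_index sweep position (used by block generators).
#' @param amplitude_scale extra multiplicative scale on the channel signal
#'   (rundown hook; baseline noise is not scaled).
#' @return a `sweep`.
#' @export
simulate_stochastic_sweep <- function(spec, protocol, noise = noise_model(0),
                                      seed = 1L, time = NULL,
                                      meta = recording_meta(),
                                      sweep_index = 1L,
                                      amplitude_scale = 1) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(noise, "noise_model"))
  if (is.null(time)) {
    dt <- meta$sample_interval
    time <- seq(0, protocol_end(protocol) + 0.05, by = dt)
  }
  with_seed(seed, {
    if (!is.null(spec$scheme)) {
      n_open <- gillespie_open_counts(spec$scheme, protocol,
                                      spec$n_channels, time)
    } else {
      p <- spec$popen
      stopifnot(length(p) == length(time))
      n_open <- stats::rbinom(length(time), spec$n_channels, p)
    }
    cur <- amplitude_scale * spec$single_channel_current * n_open
    if (noise$baseline_sd > 0) {
      cur <- cur + stats::rnorm(length(time), 0, noise$baseline_sd)
    }
    stim <- apply_solution_exchange(protocol, spec$exchange_time_10_90, time)
    patch_sweep(time, cur, stim, meta, sweep_index = sweep_index)
  })
}

#' Generate a multi-sweep block for fluctuation analysis
#'
#' Repeated stochastic sweeps under one protocol, emulating a run of 50-200
#' responses from a single patch. Rundown is applied multiplicatively and
#' cumulatively across sweeps (with optional jitter); per-sweep seeds are
#' derived from the master seed so the block is reproducible and individual
#' sweeps are independent.
#'
#' @param spec an `ensemble_spec`.
#' @param protocol a `stimulus_protocol`.
#' @param n_sweeps number of sweeps, >= 2.
#' @param noise a `noise_model`.
#' @param seed master seed.
#' @param time sample grid; default as in [simulate_stochastic_sweep()].
#' @param meta a `recording_meta`.
#' @return a `sweep_block`.
#' @export
generate_nsfa_block <- function(spec, protocol, n_sweeps = 70L,
                                noise = noise_model(), seed = 1L,
                                time = NULL, meta = recording_meta()) {
  stopifnot(n_sweeps >= 2L)
  if (is.null(time)) {
    time <- seq(0, protocol_end(protocol) + 0.05, by = meta$sample_interval)
  }
  scales <- with_seed(derive_seed(seed, "rundown"),
                      rundown_scales(noise, n_sweeps))
  sweeps <- lapply(seq_len(n_sweeps), function(k) {
    simulate_stochastic_sweep(spec, protocol, noise,
                              seed = derive_seed(seed, sprintf("sweep-%d", k)),
                              time = time, meta = meta, sweep_index = k,
                              amplitude_scale = scales[k])
  })
  sweep_block(sweeps, protocol)
}

#' Phenomenological recovery-curve generator
#'
#' Evaluates the configured recovery time course at each interval, adds
#' Gaussian noise and clips to [0, 1.05] (measured peak ratios can slightly
#' exceed 1).
#'
#' @param tau recovery time constant (s), > 0.
#' @param m slope, > 0.
#' @param intervals interpulse intervals (s), strictly increasing.
#' @param noise_sd Gaussian noise SD on the fraction (0 for noiseless).
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @param form recovery form, as in [fit_recovery()].
#' @return a `recovery_curve`.
#' @export
generate_recovery_fractions <- function(tau, m, intervals, noise_sd = 0,
                                        seed = 1L, form = "hh_power") {
  stopifnot(tau > 0, m > 0, all(intervals > 0))
  y <- recovery_fraction_at(intervals, tau, m, form)
  if (noise_sd > 0) {
    y <- with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
    y <- pmin(pmax(y, 0), 1.05)
  }
  recovery_curve(intervals, y)
}

#' The standard log-spaced interpulse interval design
#'
#' @param n number of intervals.
#' @param min_s,max_s interval range (s); defaults span 3 ms to 30 s.
#' @return numeric intervals.
#' @export
recovery_intervals <- function(n = 12L, min_s = 0.003, max_s = 30) {
  10^seq(log10(min_s), log10(max_s), length.out = n)
}

#' Phenomenological desensitization-decay trace
#'
#' Zero current before onset, then
#' `peak * (iss + (1 - iss) * exp(-(t - onset)/tau_des))` plus optional
#' Gaussian noise: an instantaneously activating response that decays to a
#' sustained fraction `iss`.
#'
#' @param tau_des desensitization time constant (s), > 0.
#' @param iss_fraction sustained (steady-state/peak) fraction in [0, 1].
#' @param peak peak current (pA; negative for inward).
#' @param time sample grid (s).
#' @param onset decay onset time (s).
#' @param noise_sd Gaussian noise SD (pA).
#' @param seed integer seed.
#' @param meta a `recording_meta`.
#' @return a `sweep` whose stimulus channel marks the application epoch
#'   (pH 5 during the decay, pH 8 at rest).
#' @export
generate_decay_trace <- function(tau_des, iss_fraction = 0, peak = -100,
                                 time = seq(0, 1.6, by = 1e-4),
                                 onset = 0.1, noise_sd = 0, seed = 1L,
                                 meta = recording_meta()) {
  stopifnot(tau_des > 0, iss_fraction >= 0, iss_fraction <= 1)
  cur <- numeric(length(time))
  on <- time >= onset
  cur[on] <- peak * (iss_fraction +
                       (1 - iss_fraction) * exp(-(time[on] - onset) / tau_des))
  if (noise_sd > 0) {
    cur <- with_seed(seed, cur + stats::rnorm(length(cur), 0, noise_sd))
  }
  stim <- ifelse(on, 5, 8)
  patch_sweep(time, cur, stim, meta)
}
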