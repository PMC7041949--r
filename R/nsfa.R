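#' Longest stable stretch of sweeps
#'
#' Fluctuation analysis requires the population response not to run down:
#' this selects the longest contiguous run of sweeps whose peak amplitudes
#' vary by no more than `tolerance` (max/min of |peak| <= 1 + tolerance,
#' the 10% stability criterion by default). Ties break toward the earliest
#' run.
#'
#' @param block a `sweep_block` with >= 2 sweeps; the protocol must carry
#'   at least one labeled epoch (`test` or `conditioning`) to locate peaks.
#' @param tolerance allowed fractional spread (default 0.10).
#' @return integer vector of sweep indices (contiguous).
#' @export
select_stable_stretch <- function(block, tolerance = 0.10) {
  stopifnot(inherits(block, "sweep_block"), n_sweeps(block) >= 2L,
            is_number(tolerance), tolerance >= 0)
  peaks <- abs(block_peaks(block))
  n <- length(peaks)
  best <- NULL
  for (i in seq_len(n - 1L)) {
    lo <- peaks[i]; hi <- peaks[i]
    for (j in (i + 1L):n) {
      lo <- min(lo, peaks[j]); hi <- max(hi, peaks[j])
      if (hi > lo * (1 + tolerance) + 1e-12) break
      if (is.null(best) || (j - i) > (best[2L] - best[1L])) best <- c(i, j)
    }
  }
  if (is.null(best)) {
    stop("no stable run of >= 2 sweeps within tolerance; record more data")
  }
  seq.int(best[1L], best[2L])
}

# |peak| of each sweep within the first labeled stimulation epoch
block_peaks <- function(block, smooth = 3L) {
  prot <- block$protocol
  e <- find_epoch(prot, "test") %||% find_epoch(prot, "conditioning") %||%
    prot$epochs[[1L]]
  time <- block$sweeps[[1L]]$time
  w <- epoch_index_window(e, time)
  wb <- c(1L, max(2L, w[1L]))
  vapply(block$sweeps, measure_epoch_peak, numeric(1), window = w,
         baseline_window = wb, smooth = smooth)
}

#' Flag sweeps with spurious variance
#'
#' Removes individual traces contaminated by brief electrical artifacts:
#' a sweep is excluded when its within-sweep successive-difference variance
#' is a robust (median/MAD) z-score outlier beyond `z_threshold`. The
#' filter iterates to convergence (at most 5 passes).
#'
#' @param block a `sweep_block` with >= 3 sweeps.
#' @param z_threshold robust z cutoff (default 5; `Inf` disables).
#' @return integer vector of retained sweep indices.
#' @export
exclude_artifact_sweeps <- function(block, z_threshold = 5) {
  stopifnot(inherits(block, "sweep_block"), n_sweeps(block) >= 3L)
  # successive-difference variance within each sweep: robust to the slow
  # response waveform, sensitive to single-sample spikes
  v <- vapply(block$sweeps, function(s) {
    d <- diff(s$current)
    mean(d^2) / 2
  }, numeric(1))
  keep <- seq_along(v)
  for (pass in seq_len(5L)) {
    med <- stats::median(v[keep])
    mad <- stats::mad(v[keep])
    # MAD degenerates to 0 on (near-)noiseless data; floor the scale so a
    # genuine spike still registers while identical sweeps never do
    scale <- max(mad, 1e-9 * max(med, 1))
    z <- (v[keep] - med) / scale
    bad <- z > z_threshold
    if (!any(bad)) break
    keep <- keep[!bad]
  }
  keep
}

#' Successive-trace pairwise variance
#'
#' The rundown-resistant ensemble variance: per time point,
#' `delta_i^2(t) = (T_{i+1}(t) - T_i(t))^2 / 2` for each successive pair,
#' averaged over the M - 1 pairs. Computing the variance from successive
#' differences rather than the global average cancels slow drift in
#' amplitude or baseline. The mean current is the plain average over the
#' sweeps used.
#'
#' @param block a `sweep_block`.
#' @param use integer sweep indices to include (default all), e.g. the
#'   output of [select_stable_stretch()] intersected with
#'   [exclude_artifact_sweeps()].
#' @return a `variance_trace`: data.frame with `time`, `mean_current`,
#'   `ensemble_variance`, plus attribute `n_pairs`.
#' @export
pairwise_variance <- function(block, use = seq_len(n_sweeps(block))) {
  stopifnot(inherits(block, "sweep_block"))
  if (length(use) < 2L) stop("need >= 2 sweeps after filtering")
  cur <- block_current_matrix(block)[, use, drop = FALSE]
  d <- cur[, -1L, drop = FALSE] - cur[, -ncol(cur), drop = FALSE]
  ev <- rowMeans(d^2) / 2
  out <- data.frame(time = block$sweeps[[1L]]$time,
                    mean_current = rowMeans(cur),
                    ensemble_variance = ev)
  attr(out, "n_pairs") <- ncol(cur) - 1L
  class(out) <- c("variance_trace", "data.frame")
  out
}

#' Baseline variance before agonist application
#'
#' Mean of the pairwise ensemble variance over a window (default 50 ms)
#' ending where the first non-rest epoch begins.
#'
#' @param block a `sweep_block`.
#' @param use sweep indices, as in [pairwise_variance()].
#' @param window window length (s), > 0; must fit before the first epoch.
#' @return baseline variance (pA^2).
#' @export
baseline_variance <- function(block, use = seq_len(n_sweeps(block)),
                              window = 0.050) {
  stopifnot(is_number(window))
  if (window <= 0) stop("baseline window must be > 0")
  if (length(block$protocol$epochs) == 0L) stop("protocol has no epochs")
  t0 <- block$protocol$epochs[[1L]]$start
  if (window > t0 + 1e-12) {
    stop("baseline window extends into the stimulation epoch")
  }
  vt <- pairwise_variance(block, use)
  sel <- vt$time >= t0 - window - 1e-12 & vt$time < t0 - 1e-12
  mean(vt$ensemble_variance[sel])
}

#' Bin a variance trace uniformly in current amplitude
#'
#' Divides the relaxation into bins whose edges are uniform in |mean
#' current| between baseline and peak. On an exponential decay this yields
#' progressively larger time bins while equalizing information per bin.
#' Empty bins are dropped.
#'
#' @param trace a `variance_trace`.
#' @param window 1-based half-open index window of the stimulation epoch
#'   over which to bin (typically peak to epoch end).
#' @param n_bins number of bins, >= 3 (default 10).
#' @param min_snr minimal (peak - baseline) / baseline-noise ratio; below
#'   it the trace has no usable dynamic range and an error is raised.
#' @return data.frame with `binned_current` (pA), `binned_variance` (pA^2),
#'   `n_samples` per bin.
#' @export
bin_current_variance <- function(trace, window, n_bins = 10L, min_snr = 3) {
  stopifnot(inherits(trace, "variance_trace"), n_bins >= 3L,
            length(window) == 2L, window[2L] > window[1L])
  idx <- window[1L]:(window[2L] - 1L)
  I <- trace$mean_current[idx]
  V <- trace$ensemble_variance[idx]
  pre <- seq_len(max(window[1L] - 1L, 1L))
  base_mean <- mean(trace$mean_current[pre])
  base_sd <- stats::sd(trace$mean_current[pre])
  rng <- max(abs(I - base_mean))
  if (rng == 0) stop("no dynamic range: current indistinguishable from baseline")
  if (is.finite(base_sd) && base_sd > 0 && rng / base_sd < min_snr) {
    stop(sprintf("peak not distinguishable from baseline (SNR %.2f < %g)",
                 rng / base_sd, min_snr))
  }
  amp <- abs(I - base_mean)
  edges <- seq(0, max(amp), length.out = n_bins + 1L)
  bin <- findInterval(amp, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  keep <- tapply(seq_along(bin), bin, identity)
  out <- data.frame(
    binned_current = vapply(keep, function(ii) mean(I[ii]), numeric(1)),
    binned_variance = vapply(keep, function(ii) mean(V[ii]), numeric(1)),
    n_samples = vapply(keep, length, integer(1)))
  rownames(out) <- NULL
  out[order(abs(out$binned_current)), , drop = FALSE]
}

#' Fit the current-variance parabola
#'
#' Least-squares fit of `sigma^2(I) = i*I - I^2/N + sigma_baseline^2` to the
#' binned pairs, with the baseline variance fixed at its measured value (it
#' is an additive measured term, not a free parameter; set `free_baseline`
#' to release it). The model is linear in (i, 1/N), so the fit is ordinary
#' unweighted least squares. Sign conventions follow the current: for
#' inward (negative) currents the fitted single-channel current is
#' negative.
#'
#' @param binned data.frame from [bin_current_variance()], >= 3 bins.
#' @param baseline measured baseline variance (pA^2).
#' @param meta a `recording_meta`; supplies the holding potential (and
#'   reversal potential, default 0 mV) for the conductance conversion.
#' @param peak_current stable-stretch mean peak current (pA) used for the
#'   peak open probability; default: the largest-|I| binned current.
#' @param free_baseline logical; also estimate the baseline variance.
#' @return an `nsfa_result`: list with `i_single` (pA), `n_channels`,
#'   `baseline_variance`, `peak_open_probability`, `conductance_pS`,
#'   `fit_rss`, `low_confidence` (TRUE when the variance is still rising at
#'   the largest |I|, i.e. open probability stays below 0.5 and the
#'   parabola vertex is extrapolated).
#' @export
fit_current_variance <- function(binned, baseline, meta = recording_meta(),
                                 peak_current = NULL,
                                 free_baseline = FALSE) {
  stopifnot(nrow(binned) >= 3L, is_number(baseline))
  I <- binned$binned_current
  V <- binned$binned_variance
  if (free_baseline) {
    fit <- stats::lm(V ~ 1 + I + I(I^2))
    cf <- stats::coef(fit)
    baseline <- unname(cf[1L])
    a <- unname(cf[2L]); b <- unname(cf[3L])
  } else {
    y <- V - baseline
    fit <- stats::lm(y ~ 0 + I + I(I^2))
    cf <- stats::coef(fit)
    a <- unname(cf[1L]); b <- unname(cf[2L])
  }
  i_single <- a
  if (b >= 0) stop("fitted channel count is not positive (variance curves upward)")
  n_channels <- -1 / b
  if (n_channels <= 0) stop("fitted channel count is not positive")
  if (is.null(peak_current)) peak_current <- I[which.max(abs(I))]
  popen <- abs(peak_current) / abs(i_single * n_channels)
  if (popen > 1.05) {
    warning(sprintf("peak open probability %.3f exceeds 1.05; fit suspect",
                    popen))
  }
  erev <- if (is.na(meta$reversal_potential)) 0 else meta$reversal_potential
  cond_pS <- 1000 * i_single / (meta$holding_potential - erev)
  vertex_I <- i_single * n_channels / 2
  low_conf <- max(abs(I)) < abs(vertex_I)
  structure(list(i_single = i_single, n_channels = n_channels,
                 baseline_variance = baseline,
                 peak_open_probability = popen,
                 conductance_pS = cond_pS,
                 fit_rss = sum(stats::resid(fit)^2),
                 low_confidence = low_conf,
                 binned = binned, peak_current = peak_current),
            class = "nsfa_result")
}

#' @export
print.nsfa_result <- function(x, ...) {
  cat(sprintf(paste0("<nsfa_result> i = %.3g pA, N = %.3g, P_open(peak) = %.3f,",
                     " g = %.3g pS, baseline %.3g pA^2%s\n"),
              x$i_single, x$n_channels, x$peak_open_probability,
              x$conductance_pS, x$baseline_variance,
              if (x$low_confidence) " [low confidence: P_open < 0.5 throughout]"
              else ""))
  invisible(x)
}

#' Full non-stationary fluctuation analysis of a sweep block
#'
#' Chains the pipeline: stability filtering (longest stretch with peaks
#' within `tolerance`), artifact exclusion, successive-trace pairwise
#' variance, baseline variance from the pre-application window, uniform
#' current-amplitude binning over the decay (peak to epoch end), and the
#' parabola fit. The peak open probability uses the stable-stretch mean
#' peak current.
#'
#' @param block a `sweep_block` whose protocol carries one application
#'   epoch.
#' @param tolerance stability tolerance, see [select_stable_stretch()].
#' @param n_bins number of current bins.
#' @param baseline_window baseline window (s).
#' @param z_threshold artifact threshold, see [exclude_artifact_sweeps()].
#' @return an `nsfa_result` with the retained sweep indices in
#'   `$sweeps_used`.
#' @export
nsfa <- function(block, tolerance = 0.10, n_bins = 10L,
                 baseline_window = 0.050, z_threshold = 5) {
  stable <- select_stable_stretch(block, tolerance)
  clean <- exclude_artifact_sweeps(block, z_threshold)
  use <- intersect(stable, clean)
  if (length(use) < 2L) stop("fewer than 2 sweeps survive filtering")
  vt <- pairwise_variance(block, use)
  bv <- baseline_variance(block, use, window = baseline_window)
  e <- block$protocol$epochs[[1L]]
  time <- block$sweeps[[1L]]$time
  w <- epoch_index_window(e, time)
  # bin from the ensemble-mean peak to the epoch end (the decay limb)
  seg <- w[1L]:(w[2L] - 1L)
  pk <- seg[which.max(abs(vt$mean_current[seg] -
                            mean(vt$mean_current[seq_len(w[1L] - 1L)])))]
  binned <- bin_current_variance(vt, c(pk, w[2L]), n_bins = n_bins)
  peaks <- block_peaks(block)[use]
  res <- fit_current_variance(binned, bv, meta = block$sweeps[[1L]]$meta,
                              peak_current = mean(peaks))
  res$sweeps_used <- use
  res
}
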