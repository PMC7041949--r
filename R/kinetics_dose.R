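#' Fit exponential decay of desensitization
#'
#' Fits `I(t) = offset + sum_k a_k * exp(-(t - t0)/tau_k)` over the decay
#' limb of an application epoch. The fit window starts at the first sample
#' after the peak where |I| has fallen below 95% of the peak (skipping the
#' activation-desensitization cusp; configurable) and runs to the epoch
#' end. For two-component fits the components are ordered fast to slow and
#' the desensitization time constant `tau_des` reports the
#' dominant-amplitude component.
#'
#' @param sw a `sweep`.
#' @param window 1-based half-open index window of the application epoch.
#' @param n_components 1 or 2.
#' @param start_fraction fraction of |peak| at which the fit window opens
#'   (default 0.95).
#' @param baseline_window index window for baseline subtraction; defaults
#'   to everything before the epoch.
#' @return a `decay_fit`: list with `tau_components` (s), `amplitudes`
#'   (pA), `offset` (pA), `tau_des`, `n_components`, `fit_window`, flags
#'   `no_decay` (amplitude ~ 0) and `tau_at_bound`.
#' @export
fit_exponential_decay <- function(sw, window, n_components = 1L,
                                  start_fraction = 0.95,
                                  baseline_window = NULL) {
  stopifnot(inherits(sw, "sweep"), length(window) == 2L,
            n_components %in% c(1L, 2L))
  if (is.null(baseline_window)) baseline_window <- c(1L, max(2L, window[1L]))
  base <- mean(sw$current[baseline_window[1L]:(baseline_window[2L] - 1L)])
  idx <- window[1L]:(window[2L] - 1L)
  x <- sw$current[idx] - base
  pk_rel <- which.max(abs(x))
  pk_val <- abs(x[pk_rel])
  if (pk_val == 0) stop("no resolvable peak in the epoch")
  after <- which(abs(x) < start_fraction * pk_val &
                   seq_along(x) > pk_rel)
  if (length(after) == 0L) {
    fit_start <- pk_rel
  } else {
    fit_start <- after[1L]
  }
  fit_idx <- fit_start:length(x)
  if (length(fit_idx) < 10L) stop("decay fit window shorter than 10 samples")
  tt <- sw$time[idx][fit_idx] - sw$time[idx][fit_start]
  yy <- x[fit_idx]
  span <- max(tt)
  sgn <- sign(yy[1L])
  a0 <- abs(yy[1L])
  tau_grid <- span / c(100, 30, 10, 3, 1)
  best <- NULL
  for (tau0 in tau_grid) {
    fit <- tryCatch({
      if (n_components == 1L) {
        minpack.lm::nlsLM(
          yy ~ off + a1 * exp(-tt / tau1),
          start = list(off = yy[length(yy)], a1 = sgn * a0, tau1 = tau0),
          lower = c(off = -Inf, a1 = -Inf, tau1 = span * 1e-5),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          yy ~ off + a1 * exp(-tt / tau1) + a2 * exp(-tt / tau2),
          start = list(off = yy[length(yy)], a1 = sgn * a0 * 0.6,
                       tau1 = tau0 / 5, a2 = sgn * a0 * 0.4, tau2 = tau0 * 2),
          lower = c(off = -Inf, a1 = -Inf, tau1 = span * 1e-5,
                    a2 = -Inf, tau2 = span * 1e-5),
          control = minpack.lm::nls.lm.control(maxiter = 400))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("exponential decay fit failed from every start")
  cf <- stats::coef(best$fit)
  if (n_components == 1L) {
    taus <- unname(cf["tau1"]); amps <- unname(cf["a1"])
  } else {
    taus <- unname(c(cf["tau1"], cf["tau2"]))
    amps <- unname(c(cf["a1"], cf["a2"]))
    o <- order(taus)
    taus <- taus[o]; amps <- amps[o]
  }
  tau_des <- taus[which.max(abs(amps))]
  structure(list(tau_components = taus, amplitudes = amps,
                 offset = unname(cf["off"]), tau_des = tau_des,
                 n_components = n_components,
                 fit_window = c(idx[fit_start], window[2L]),
                 no_decay = max(abs(amps)) < 0.01 * (pk_val + abs(cf["off"])),
                 tau_at_bound = any(taus > span * 3),
                 rss = best$rss),
            class = "decay_fit")
}

#' 10-90% rise time of an activating response
#'
#' Time between the last 10% crossing and the first 90% crossing of
#' |peak - baseline| preceding the peak, with linear interpolation between
#' samples.
#'
#' @param sw a `sweep`.
#' @param window 1-based half-open index window of the epoch.
#' @param baseline_window baseline index window (defaults to pre-epoch).
#' @return rise time (s).
#' @export
rise_time_10_90 <- function(sw, window, baseline_window = NULL) {
  stopifnot(inherits(sw, "sweep"), length(window) == 2L)
  if (is.null(baseline_window)) baseline_window <- c(1L, max(2L, window[1L]))
  base <- mean(sw$current[baseline_window[1L]:(baseline_window[2L] - 1L)])
  idx <- window[1L]:(window[2L] - 1L)
  x <- abs(sw$current[idx] - base)
  tt <- sw$time[idx]
  pk <- which.max(x)
  amp <- x[pk]
  if (amp == 0) stop("no resolvable peak")
  rise <- x[1:pk]
  cross_t <- function(level) {
    above <- rise >= level
    j <- which(above)[1L]       # first crossing of the level
    if (is.na(j)) stop("rise does not bracket the 10-90% levels")
    if (j == 1L) return(tt[1L])
    # linear interpolation between samples j-1 and j
    f <- (level - rise[j - 1L]) / (rise[j] - rise[j - 1L])
    tt[j - 1L] + f * (tt[j] - tt[j - 1L])
  }
  # last 10% crossing = first crossing when scanning back from the peak
  below10 <- which(rise[1:pk] < 0.1 * amp)
  t10 <- if (length(below10) == 0L) tt[1L] else {
    j <- below10[length(below10)]
    if (j == pk) stop("non-monotone rise: cannot bracket 10% crossing")
    f <- (0.1 * amp - rise[j]) / (rise[j + 1L] - rise[j])
    tt[j] + f * (tt[j + 1L] - tt[j])
  }
  t90 <- cross_t(0.9 * amp)
  if (t90 < t10) stop("non-monotone rise: 90% crossing precedes 10% crossing")
  t90 - t10
}

#' Sustained over peak current
#'
#' Mean baseline-subtracted current over the last 5% of the application
#' epoch divided by the peak current.
#'
#' @param sw a `sweep`.
#' @param window 1-based half-open index window of the epoch (>= 100 ms).
#' @param baseline_window baseline index window.
#' @param noise_floor minimum |peak| (pA).
#' @return Iss/Ipeak (unitless).
#' @export
iss_over_ipeak <- function(sw, window, baseline_window = NULL,
                           noise_floor = 0) {
  stopifnot(inherits(sw, "sweep"), length(window) == 2L)
  dt <- sw$meta$sample_interval
  if ((window[2L] - window[1L]) * dt < 0.1) {
    stop("epoch must be at least 100 ms for a steady-state estimate")
  }
  if (is.null(baseline_window)) baseline_window <- c(1L, max(2L, window[1L]))
  base <- mean(sw$current[baseline_window[1L]:(baseline_window[2L] - 1L)])
  idx <- window[1L]:(window[2L] - 1L)
  x <- sw$current[idx] - base
  pk <- x[which.max(abs(x))]
  if (abs(pk) <= noise_floor) stop("peak below noise floor")
  n <- length(x)
  ss <- mean(x[ceiling(0.95 * n):n])
  ss / pk
}

#' Fold change of the sustained current relative to pH 5
#'
#' `(Iss/Ipeak)_test / (Iss/Ipeak)_reference`, quantifying how a sustained
#' (non-desensitizing) current emerges at pH values below 5.
#'
#' @param test,reference lists or rows with an `iss_over_ipeak` field; the
#'   reference is the pH 5 measurement.
#' @return unitless fold change.
#' @export
sustained_fold_change <- function(test, reference) {
  rt <- test$iss_over_ipeak
  rr <- reference$iss_over_ipeak
  stopifnot(is_number(rt), is_number(rr))
  if (rr == 0) stop("reference Iss/Ipeak is zero")
  rt / rr
}

#' Normalize interleaved dose-response peaks
#'
#' Test-pH applications are interleaved with pH 5 reference applications on
#' either side to control for rundown: each test peak is divided by the
#' mean of its two flanking reference peaks.
#'
#' @param peaks numeric peak currents (pA), in recording order.
#' @param labels character vector: `"ref"` for reference (pH 5)
#'   applications, otherwise the test pH as text (e.g. `"6.6"`).
#' @return data.frame with `ph` and `normalized_peak`, one row per test
#'   application.
#' @export
normalize_interleaved <- function(peaks, labels) {
  stopifnot(length(peaks) == length(labels))
  is_test <- labels != "ref"
  out <- list()
  for (j in which(is_test)) {
    left <- rev(which(!is_test & seq_along(peaks) < j))
    right <- which(!is_test & seq_along(peaks) > j)
    if (length(left) == 0L || length(right) == 0L) {
      stop(sprintf("test response %d is not flanked by references", j))
    }
    flank <- mean(c(peaks[left[1L]], peaks[right[1L]]))
    out[[length(out) + 1L]] <- data.frame(
      ph = as.numeric(labels[j]),
      normalized_peak = abs(peaks[j]) / abs(flank))
  }
  do.call(rbind, out)
}

#' Fit a proton dose-response (Hill) curve
#'
#' Least-squares fit of `I(pH) = 1 / (1 + 10^(n * (pH - pH50)))`, oriented
#' so that acidification increases the response; the predicted response at
#' pH50 is exactly 0.5 and the maximum is fixed at 1.
#'
#' @param points data.frame with `ph` and `normalized_peak`, >= 4 points
#'   spanning the transition.
#' @return a `hill_fit`: list with `ph50`, `hill_n`, `rss`.
#' @export
fit_hill <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 4L,
            all(c("ph", "normalized_peak") %in% names(points)))
  ph <- points$ph
  y <- points$normalized_peak
  if (max(y) < 0.6 || min(y) > 0.4) {
    stop("no transition in range: responses do not span the half-maximum")
  }
  # starting pH50: interpolated half-maximum crossing
  o <- order(ph)
  ph50_0 <- stats::approx(y[o], ph[o], xout = 0.5, ties = mean)$y
  if (is.na(ph50_0)) ph50_0 <- stats::median(ph)
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4, 8)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + 10^(n * (ph - ph50))),
                        start = list(ph50 = ph50_0, n = n0),
                        lower = c(ph50 = min(ph) - 2, n = 1e-3),
                        upper = c(ph50 = max(ph) + 2, n = 100),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(ph50 = unname(cf["ph50"]), hill_n = unname(cf["n"]),
                   rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed from every start")
  structure(best, class = "hill_fit")
}

#' Predicted Hill-curve response
#'
#' @param ph pH values.
#' @param ph50 half-maximal pH.
#' @param hill_n Hill slope, > 0.
#' @return normalized response in (0, 1).
#' @export
hill_response <- function(ph, ph50, hill_n) {
  stopifnot(hill_n > 0)
  1 / (1 + 10^(hill_n * (ph - ph50)))
}

#' Peak and sustained-current trajectories across a sweep series
#'
#' For experiments that track the response before, during and after a
#' treatment (e.g. UV photo-trapping), normalizes each sweep's peak to the
#' mean peak of the pre-treatment baseline sweeps, and reports Iss/Ipeak
#' per sweep.
#'
#' @param block a `sweep_block` in recording order; the protocol must carry
#'   one application epoch.
#' @param n_baseline number of initial baseline sweeps (>= 1).
#' @return data.frame with `sweep_index`, `normalized_peak`,
#'   `iss_over_ipeak`.
#' @export
sweep_series_peaks <- function(block, n_baseline = 1L) {
  stopifnot(inherits(block, "sweep_block"), n_baseline >= 1L,
            n_baseline <= n_sweeps(block))
  peaks <- block_peaks(block)
  e <- block$protocol$epochs[[1L]]
  time <- block$sweeps[[1L]]$time
  w <- epoch_index_window(e, time)
  ratios <- vapply(block$sweeps, iss_over_ipeak, numeric(1), window = w)
  ref <- mean(abs(peaks[seq_len(n_baseline)]))
  data.frame(sweep_index = seq_along(peaks),
             normalized_peak = abs(peaks) / ref,
             iss_over_ipeak = ratios)
}
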