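#' Recovery-from-desensitization curve
#'
#' Fraction of the conditioning-pulse peak recovered at each interpulse
#' interval. Measured ratios can slightly exceed 1 on noisy data, so
#' fractions are allowed up to 1.1.
#'
#' @param interval interpulse intervals (s), strictly increasing.
#' @param fraction test peak / conditioning peak per interval, in [0, 1.1].
#' @param n_repeats_averaged integer repeats averaged per point.
#' @return a `recovery_curve` object (also a data.frame).
#' @export
recovery_curve <- function(interval, fraction,
                           n_repeats_averaged = rep(1L, length(interval))) {
  stopifnot(is.numeric(interval), is.numeric(fraction),
            length(interval) == length(fraction),
            length(n_repeats_averaged) == length(interval))
  if (is.unsorted(interval, strictly = TRUE)) {
    stop("intervals must be strictly increasing")
  }
  if (any(fraction < 0 | fraction > 1.1)) {
    stop("fractions must lie in [0, 1.1]")
  }
  structure(data.frame(interval = interval, fraction = fraction,
                       n_repeats_averaged = as.integer(n_repeats_averaged)),
            class = c("recovery_curve", "data.frame"))
}

#' Peak current within an epoch window
#'
#' Returns the signed extremum of the baseline-subtracted current within
#' the window; with inward currents negative, a downward response yields a
#' negative peak. A short boxcar pre-smoothing (default 3 samples) guards
#' single-sample noise spikes.
#'
#' @param sw a `sweep`.
#' @param window 1-based half-open index window `c(start, end)` of the
#'   epoch.
#' @param baseline_window index window preceding the epoch used for the
#'   baseline estimate (its mean current).
#' @param smooth boxcar width in samples (odd; 1 disables smoothing).
#' @return peak current in pA (signed, baseline-subtracted).
#' @export
measure_epoch_peak <- function(sw, window, baseline_window, smooth = 3L) {
  stopifnot(inherits(sw, "sweep"), length(window) == 2L,
            length(baseline_window) == 2L,
            baseline_window[2L] <= window[1L],
            window[1L] >= 1L, window[2L] <= length(sw$current) + 1L,
            window[2L] > window[1L])
  if (window[2L] - window[1L] < smooth) {
    stop("epoch window shorter than the smoothing kernel")
  }
  base <- mean(sw$current[baseline_window[1L]:(baseline_window[2L] - 1L)])
  x <- sw$current[window[1L]:(window[2L] - 1L)] - base
  if (smooth > 1L) {
    x <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
    x <- x[!is.na(x)]
  }
  x[which.max(abs(x))]
}

# locate labeled epoch windows + a baseline window on a sweep grid
labeled_windows <- function(block) {
  prot <- block$protocol
  time <- block$sweeps[[1L]]$time
  cond <- find_epoch(prot, "conditioning")
  test <- find_epoch(prot, "test")
  if (is.null(cond) || is.null(test)) {
    stop("protocol must carry labeled conditioning and test epochs")
  }
  wc <- epoch_index_window(cond, time)
  wt <- epoch_index_window(test, time)
  wb <- c(1L, max(2L, wc[1L]))
  list(cond = wc, test = wt, base = wb,
       interval = test$start - (cond$start + cond$duration))
}

#' Fraction recovered from a paired-pulse sweep block
#'
#' For each sweep, measures the conditioning and test peaks and forms the
#' ratio test/conditioning; repeats at the same interpulse interval are
#' averaged into one point. The interval is read from the protocol as
#' conditioning end to test start. Sweeps whose conditioning peak falls
#' below `noise_floor` are dropped with a message.
#'
#' @param blocks a `sweep_block`, or a list of them (one per interval).
#' @param noise_floor minimum |conditioning peak| (pA) for a usable sweep.
#' @param smooth boxcar width passed to [measure_epoch_peak()].
#' @return a `recovery_curve`.
#' @export
fraction_recovered <- function(blocks, noise_floor = 0, smooth = 3L) {
  if (inherits(blocks, "sweep_block")) blocks <- list(blocks)
  pts <- list()
  for (block in blocks) {
    w <- labeled_windows(block)
    for (sw in block$sweeps) {
      pc <- measure_epoch_peak(sw, w$cond, w$base, smooth = smooth)
      pt <- measure_epoch_peak(sw, w$test, w$base, smooth = smooth)
      if (abs(pc) <= noise_floor) {
        message(sprintf("sweep %d dropped: conditioning peak %.3g pA below noise floor",
                        sw$sweep_index, pc))
        next
      }
      pts[[length(pts) + 1L]] <- c(interval = w$interval,
                                   fraction = pt / pc)
    }
  }
  if (length(pts) == 0L) stop("no usable sweeps")
  df <- as.data.frame(do.call(rbind, pts))
  agg_f <- tapply(df$fraction, df$interval, mean)
  agg_n <- tapply(df$fraction, df$interval, length)
  iv <- as.numeric(names(agg_f))
  o <- order(iv)
  recovery_curve(iv[o], pmin(as.numeric(agg_f)[o], 1.1),
                 as.integer(agg_n)[o])
}

# the two selectable recovery time-course forms; both reduce to the
# mono-exponential 1 - exp(-t/tau) at m = 1
recovery_form_fn <- function(form = c("hh_power", "stretched_exp")) {
  form <- match.arg(form)
  if (form == "hh_power") {
    function(t, tau, m) (1 - exp(-t / tau))^m
  } else {
    function(t, tau, m) 1 - exp(-(t / tau)^m)
  }
}

#' Evaluate the recovery time course
#'
#' `hh_power` is the Hodgkin-Huxley activation form `(1 - exp(-t/tau))^m`
#' (the default; steep recoveries need m >> 1); `stretched_exp` is
#' `1 - exp(-(t/tau)^m)`.
#'
#' @param t time (s).
#' @param tau recovery time constant (s), > 0.
#' @param m slope, > 0.
#' @param form functional form.
#' @return fraction recovered in [0, 1).
#' @export
recovery_fraction_at <- function(t, tau, m, form = "hh_power") {
  stopifnot(tau > 0, m > 0)
  recovery_form_fn(form)(t, tau, m)
}

#' Fit the recovery time course
#'
#' Nonlinear least squares of fraction recovered versus interpulse interval.
#' Because steep-slope recoveries (m of 9-10) have deceptive mono-exponential
#' local minima, the fit is multi-started over a decade grid of tau spanning
#' the interval range crossed with m in {0.5, 1, 2, 5, 10}; the best-RSS
#' convergent start wins. The asymptote is fixed at 1 (the functional form
#' dictates full recovery); measured fractions above 1 are not clipped.
#'
#' @param curve a `recovery_curve` (or data.frame with `interval`,
#'   `fraction`), >= 4 points (>= 2 when `constrain_m1`).
#' @param form `"hh_power"` (default) or `"stretched_exp"`.
#' @param constrain_m1 logical; fix m = 1 (mono-exponential fit).
#' @return a `recovery_fit`: list with `tau` (s), `m`, `form`, `rss`,
#'   `n_points`, `constrained`.
#' @export
fit_recovery <- function(curve, form = c("hh_power", "stretched_exp"),
                         constrain_m1 = FALSE) {
  form <- match.arg(form)
  t <- curve$interval
  y <- curve$fraction
  min_pts <- if (constrain_m1) 2L else 4L
  if (length(t) < min_pts) stop("need at least ", min_pts, " points")
  fn <- recovery_form_fn(form)
  tau_grid <- 10^seq(floor(log10(min(t))) - 1, ceiling(log10(max(t))) + 1)
  m_grid <- if (constrain_m1) 1 else c(0.5, 1, 2, 5, 10)
  best <- NULL
  diag_msgs <- character(0)
  for (tau0 in tau_grid) {
    for (m0 in m_grid) {
      fit <- tryCatch({
        if (constrain_m1) {
          minpack.lm::nlsLM(y ~ fn(t, tau, 1), start = list(tau = tau0),
                            lower = c(tau = 1e-12),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
        } else {
          minpack.lm::nlsLM(y ~ fn(t, tau, m),
                            start = list(tau = tau0, m = m0),
                            lower = c(tau = 1e-12, m = 1e-6),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
        }
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        diag_msgs <- c(diag_msgs,
                       sprintf("tau0=%.3g m0=%.3g: %s", tau0, m0,
                               conditionMessage(fit)))
        next
      }
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-15) {
        cf <- stats::coef(fit)
        best <- list(tau = unname(cf["tau"]),
                     m = if (constrain_m1) 1 else unname(cf["m"]),
                     form = form, rss = rss, n_points = length(t),
                     constrained = constrain_m1)
      }
    }
  }
  if (is.null(best)) {
    stop("recovery fit failed from every start:\n",
         paste(diag_msgs, collapse = "\n"))
  }
  structure(best, class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit %s> tau = %.4g s, m = %.3g (rss %.3g, n %d)%s\n",
              x$form, x$tau, x$m, x$rss, x$n_points,
              if (x$constrained) " [m fixed at 1]" else ""))
  invisible(x)
}

#' Summarize per-patch recovery fits
#'
#' Patches are fit individually and the fitted parameters averaged; n is
#' the number of patches.
#'
#' @param fits list of `recovery_fit`.
#' @return list with `tau` and `m`, each a [mean_sem()] summary.
#' @export
summarize_fits <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "recovery_fit")))
  list(tau = mean_sem(vapply(fits, `[[`, numeric(1), "tau")),
       m = mean_sem(vapply(fits, `[[`, numeric(1), "m")))
}

#' Correlation between recovery speed and steepness
#'
#' Pearson correlation between log10(tau) and log10(m) across fits; faster
#' recoveries pairing with steeper slopes give a negative r.
#'
#' @param fits list of `recovery_fit`, length >= 3.
#' @return Pearson correlation coefficient.
#' @export
tau_slope_correlation <- function(fits) {
  stopifnot(length(fits) >= 3L)
  lt <- log10(vapply(fits, `[[`, numeric(1), "tau"))
  lm_ <- log10(vapply(fits, `[[`, numeric(1), "m"))
  if (stats::sd(lt) == 0 || stats::sd(lm_) == 0) {
    stop("zero variance in log(tau) or log(m)")
  }
  stats::cor(lt, lm_)
}
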