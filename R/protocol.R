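#' Stimulus epochs and protocols
#'
#' A stimulus protocol is an ordered, non-overlapping list of constant-pH
#' epochs laid over a resting pH. Epoch labels follow the paired-pulse
#' vocabulary of ASIC recovery experiments: a long acidic `conditioning`
#' pulse that desensitizes the channels, an `interpulse` recovery period at
#' rest pH, and a brief acidic `test` pulse whose peak, relative to the
#' conditioning peak, measures the fraction of channels recovered.
#'
#' @param start epoch start time (s).
#' @param duration epoch duration (s), > 0.
#' @param level stimulus level (pH units).
#' @param label one of `"baseline"`, `"conditioning"`, `"interpulse"`,
#'   `"test"`, `"generic"`.
#' @return `stimulus_epoch()`: a `stimulus_epoch` object.
#' @export
stimulus_epoch <- function(start, duration, level,
                           label = c("generic", "baseline", "conditioning",
                                     "interpulse", "test")) {
  label <- match.arg(label)
  stopifnot(is_number(start), start >= 0, is_number(duration), duration > 0,
            is_number(level))
  structure(list(start = start, duration = duration, level = level,
                 label = label),
            class = "stimulus_epoch")
}

#' @param epochs list of `stimulus_epoch`, time-ordered and non-overlapping.
#' @param rest_level resting pH held outside all epochs.
#' @return `stimulus_protocol()`: a `stimulus_protocol` object.
#' @rdname stimulus_epoch
#' @export
stimulus_protocol <- function(epochs, rest_level) {
  stopifnot(is.list(epochs), is_number(rest_level))
  if (length(epochs) > 0L) {
    stopifnot(all(vapply(epochs, inherits, logical(1), "stimulus_epoch")))
    starts <- vapply(epochs, `[[`, numeric(1), "start")
    ends <- starts + vapply(epochs, `[[`, numeric(1), "duration")
    if (is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1L] < ends[-length(ends)] - 1e-12)) {
      stop("epochs must be time-ordered and non-overlapping")
    }
  }
  structure(list(epochs = epochs, rest_level = rest_level),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> rest pH %.2f, %d epoch(s)\n",
              x$rest_level, length(x$epochs)))
  for (e in x$epochs) {
    cat(sprintf("  %-12s %8.4g s + %8.4g s at pH %.2f\n",
                e$label, e$start, e$duration, e$level))
  }
  invisible(x)
}

protocol_end <- function(protocol) {
  if (length(protocol$epochs) == 0L) return(0)
  e <- protocol$epochs[[length(protocol$epochs)]]
  e$start + e$duration
}

#' Render a protocol onto a uniform sample grid (ideal square steps)
#'
#' @param protocol a `stimulus_protocol`.
#' @param time numeric vector of sample times (s), uniform.
#' @return numeric stimulus samples (pH) on the grid.
#' @export
protocol_to_stimulus <- function(protocol, time) {
  stopifnot(inherits(protocol, "stimulus_protocol"), is.numeric(time))
  stim <- rep(protocol$rest_level, length(time))
  for (e in protocol$epochs) {
    idx <- time >= e$start - 1e-12 & time < e$start + e$duration - 1e-12
    stim[idx] <- e$level
  }
  stim
}

#' Standard paired-pulse recovery protocol
#'
#' The default mirrors the recovery-from-desensitization protocol used for
#' chicken ASIC1: a 1.5 s conditioning pulse into pH 5 that fully
#' desensitizes the channels, a variable interpulse interval at the rest pH
#' (pH 8), then a 500 ms test pulse of pH 5.
#'
#' @param interval interpulse interval (s), conditioning end to test start.
#' @param conditioning_duration conditioning pulse length (s).
#' @param test_duration test pulse length (s).
#' @param acid_level pH of the conditioning/test pulses.
#' @param rest_level interpulse/rest pH.
#' @param baseline baseline time before the conditioning pulse (s).
#' @return a `stimulus_protocol` with labeled epochs.
#' @export
paired_pulse_protocol <- function(interval,
                                  conditioning_duration = 1.5,
                                  test_duration = 0.5,
                                  acid_level = 5,
                                  rest_level = 8,
                                  baseline = 0.1) {
  stopifnot(is_number(interval), interval > 0)
  cond <- stimulus_epoch(baseline, conditioning_duration, acid_level,
                         "conditioning")
  test <- stimulus_epoch(baseline + conditioning_duration + interval,
                         test_duration, acid_level, "test")
  stimulus_protocol(list(cond, test), rest_level)
}

#' Single application protocol (one acidic step)
#'
#' @param duration application length (s).
#' @param acid_level applied pH.
#' @param rest_level rest pH.
#' @param baseline baseline time before the step (s); must leave room for
#'   the 50 ms baseline-variance window used by fluctuation analysis.
#' @return a `stimulus_protocol` with one labeled `test` epoch.
#' @export
application_protocol <- function(duration = 0.8, acid_level = 5,
                                 rest_level = 8, baseline = 0.1) {
  stimulus_protocol(list(stimulus_epoch(baseline, duration, acid_level,
                                        "test")),
                    rest_level)
}

# find the epoch with a given label; NULL if absent
find_epoch <- function(protocol, label) {
  for (e in protocol$epochs) if (e$label == label) return(e)
  NULL
}

# epoch -> half-open index window [start, end) on a uniform grid
epoch_index_window <- function(epoch, time) {
  dt <- time[2L] - time[1L]
  i0 <- which(time >= epoch$start - dt / 2)[1L]
  i1 <- which(time < epoch$start + epoch$duration - dt / 2)
  i1 <- if (length(i1)) i1[length(i1)] + 1L else i0
  c(i0, i1)  # 1-based [i0, i1) half-open
}
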