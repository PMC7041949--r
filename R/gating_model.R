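#' Markov kinetic scheme for channel gating
#'
#' A scheme holds an ordered state list, the subset of conducting states,
#' and one rate matrix Q per discrete pH level. `Q[a, b]` is the transition
#' rate a -> b (1/s) for a != b; diagonals are set to minus the row sums so
#' every row sums to zero. pH dependence is a lookup over the discrete
#' levels the protocols use; no continuous proton-binding law is assumed.
#'
#' @param states character vector of state labels (e.g. `c("R","C","O","D")`).
#' @param conducting character subset of `states` that carry current.
#' @param rates named list: one square matrix of off-diagonal rates per pH
#'   level, names parseable as numbers (e.g. `"5"`, `"8"`). Diagonals are
#'   overwritten.
#' @return a `kinetic_scheme` object.
#' @export
kinetic_scheme <- function(states, conducting, rates) {
  stopifnot(is.character(states), length(states) >= 2L,
            !anyDuplicated(states),
            is.character(conducting), length(conducting) >= 1L,
            all(conducting %in% states),
            is.list(rates), length(rates) >= 1L,
            !is.null(names(rates)))
  k <- length(states)
  rates <- lapply(rates, function(Q) {
    Q <- as.matrix(Q)
    if (!all(dim(Q) == k)) stop("each rate matrix must be ", k, " x ", k)
    dimnames(Q) <- list(states, states)
    diag(Q) <- 0
    if (any(Q < 0)) stop("off-diagonal rates must be >= 0")
    diag(Q) <- -rowSums(Q)
    Q
  })
  structure(list(states = states, conducting = conducting, rates = rates),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> states: %s; conducting: %s; pH levels: %s\n",
              paste(x$states, collapse = ","),
              paste(x$conducting, collapse = ","),
              paste(names(x$rates), collapse = ",")))
  invisible(x)
}

scheme_Q <- function(scheme, level) {
  key <- names(scheme$rates)[abs(as.numeric(names(scheme$rates)) - level) < 1e-9]
  if (length(key) == 0L) {
    stop(sprintf("no rate matrix defined for pH %.3g", level))
  }
  scheme$rates[[key[1L]]]
}

#' Load a kinetic scheme from a YAML config file
#'
#' Expected layout: `states` (list), `conducting` (list), `rates` (map from
#' pH level to a map `from: {to: rate}`). Validated against the scheme
#' invariants on load.
#'
#' @param path YAML file path.
#' @return a `kinetic_scheme`.
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$states), !is.null(cfg$conducting),
            !is.null(cfg$rates))
  states <- as.character(unlist(cfg$states))
  k <- length(states)
  rates <- lapply(cfg$rates, function(tbl) {
    Q <- matrix(0, k, k, dimnames = list(states, states))
    for (from in names(tbl)) {
      for (to in names(tbl[[from]])) {
        if (!(from %in% states) || !(to %in% states)) {
          stop(sprintf("rate %s->%s names an unknown state", from, to))
        }
        Q[from, to] <- as.numeric(tbl[[from]][[to]])
      }
    }
    Q
  })
  names(rates) <- names(cfg$rates)
  kinetic_scheme(states, as.character(unlist(cfg$conducting)), rates)
}

#' Built-in default gating schemes
#'
#' Two topologies are shipped because the connectivity of the desensitized
#' state in ASIC gating is itself the scientific question: `"linear"` is the
#' classic R <-> O <-> D scheme where desensitization proceeds through the
#' open state; `"branching"` is a four-state scheme (R, C, O, D) in which
#' protonation closes into C and desensitization branches off the shut
#' state C rather than O. Rates are calibrated so the branching scheme
#' desensitizes at pH 5 with tau ~ 0.18 s and recovers at pH 8 with
#' tau ~ 0.84 s, matching wild-type chicken ASIC1 kinetics; they live in a
#' YAML config under `inst/extdata/`, not in code.
#'
#' @param name `"branching"` (default, four states) or `"linear"`.
#' @return a `kinetic_scheme`.
#' @export
default_scheme <- function(name = c("branching", "linear")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("scheme_", name, ".yaml"),
                      package = "asickinetics", mustWork = TRUE)
  read_scheme_config(path)
}

#' Steady-state occupancy at a fixed pH
#'
#' Solves pi Q = 0 with sum(pi) = 1 via the null space of t(Q); used to
#' initialize protocols at the rest pH.
#'
#' @param scheme a `kinetic_scheme`.
#' @param level pH level with rates defined.
#' @return named occupancy vector (sums to 1).
#' @export
steady_state <- function(scheme, level) {
  Q <- scheme_Q(scheme, level)
  comps <- communicating_components(Q)
  if (length(comps) > 1L) {
    stop("chain is reducible at pH ", level, "; components: ",
         paste(vapply(comps, paste, character(1), collapse = ","),
               collapse = " | "))
  }
  k <- nrow(Q)
  # solve [t(Q); 1] pi = [0; 1] in least squares (exact for irreducible Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi_hat <- as.numeric(qr.solve(A, b))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  if (any(pi_hat < 0)) stop("negative steady-state occupancy; check rates")
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- scheme$states
  pi_hat
}

# strongly-connected components of the transition graph (rates > 0)
communicating_components <- function(Q) {
  k <- nrow(Q)
  adj <- Q > 0
  diag(adj) <- TRUE
  # reachability by boolean matrix powers (k is tiny)
  reach <- adj
  for (i in seq_len(k)) reach <- (reach %*% adj) > 0 | reach
  comp_id <- rep(NA_integer_, k)
  nxt <- 0L
  for (i in seq_len(k)) {
    if (is.na(comp_id[i])) {
      nxt <- nxt + 1L
      members <- which(reach[i, ] & reach[, i])
      comp_id[members] <- nxt
    }
  }
  split(rownames(Q) %||% as.character(seq_len(k)), comp_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# e^{Qt} acting on a row vector p0, via spectral decomposition with a
# scaling-and-squaring fallback for ill-conditioned eigenvector bases.
# apply_many(p0, ts) evaluates all times in one shot (rows = times).
make_propagator <- function(Q, cond_tol = 1e8) {
  eg <- eigen(Q)
  V <- eg$vectors
  condV <- tryCatch(kappa(V, exact = TRUE), error = function(e) Inf)
  if (!is.finite(condV) || condV > cond_tol) {
    f <- function(p0, ts) {
      t(vapply(ts, function(t) {
        as.numeric(p0 %*% as.matrix(Matrix::expm(Q * t)))
      }, numeric(nrow(Q))))
    }
    return(list(fallback = TRUE, apply_many = f,
                apply = function(p0, t) as.numeric(f(p0, t))))
  }
  Vinv <- solve(V)
  f <- function(p0, ts) {
    w <- p0 %*% V  # complex when Q has complex spectrum
    E <- exp(outer(ts, eg$values))          # T x k
    Re((E * matrix(w, length(ts), ncol(V), byrow = TRUE)) %*% Vinv)
  }
  list(fallback = FALSE, apply_many = f,
       apply = function(p0, t) as.numeric(f(p0, t)))
}

#' Propagate state occupancies through a piecewise-constant pH protocol
#'
#' Within each constant-pH segment the master equation dp/dt = p Q is solved
#' exactly as p(t) = p0 exp(Qt) by spectral decomposition of Q; segment-final
#' occupancies seed the next segment, so the trajectory is continuous across
#' epoch boundaries. Non-diagonalizable (or badly conditioned) Q falls back
#' to a scaling-and-squaring matrix exponential; the fallback is recorded in
#' the result.
#'
#' @param scheme a `kinetic_scheme`.
#' @param protocol a `stimulus_protocol`; all epoch levels (and the rest
#'   level) must have rates defined.
#' @param p0 initial occupancy vector; defaults to the steady state at the
#'   rest level.
#' @param output_interval output sample interval (s).
#' @param t_end end time (s); defaults to protocol end plus one output step.
#' @return an `occupancy_trajectory`: list with `time`, `occupancy` (matrix,
#'   one column per state), `open_probability`, `used_fallback`.
#' @export
propagate <- function(scheme, protocol, p0 = NULL, output_interval = 1e-3,
                      t_end = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "stimulus_protocol"),
            is_number(output_interval), output_interval > 0)
  if (is.null(p0)) p0 <- steady_state(scheme, protocol$rest_level)
  k <- length(scheme$states)
  stopifnot(length(p0) == k, all(p0 >= -1e-12), abs(sum(p0) - 1) < 1e-8)
  p0 <- pmax(p0, 0); p0 <- p0 / sum(p0)
  if (is.null(t_end)) t_end <- protocol_end(protocol) + output_interval
  # build piecewise-constant segments (rest gaps + epochs)
  segs <- list()
  cursor <- 0
  for (e in protocol$epochs) {
    if (e$start > cursor + 1e-15) {
      segs[[length(segs) + 1L]] <- list(t0 = cursor, t1 = e$start,
                                        level = protocol$rest_level)
    }
    segs[[length(segs) + 1L]] <- list(t0 = e$start, t1 = e$start + e$duration,
                                      level = e$level)
    cursor <- e$start + e$duration
  }
  if (t_end > cursor + 1e-15) {
    segs[[length(segs) + 1L]] <- list(t0 = cursor, t1 = t_end,
                                      level = protocol$rest_level)
  }
  out_time <- seq(0, t_end, by = output_interval)
  occ <- matrix(NA_real_, length(out_time), k,
                dimnames = list(NULL, scheme$states))
  used_fallback <- FALSE
  props <- list()  # cache per level
  p <- p0
  for (seg in segs) {
    key <- sprintf("%.9g", seg$level)
    if (is.null(props[[key]])) {
      props[[key]] <- make_propagator(scheme_Q(scheme, seg$level))
    }
    pr <- props[[key]]
    used_fallback <- used_fallback || pr$fallback
    sel <- which(out_time >= seg$t0 - 1e-12 & out_time < seg$t1 - 1e-12)
    if (length(sel)) {
      occ[sel, ] <- pr$apply_many(p, out_time[sel] - seg$t0)
    }
    p <- pr$apply(p, seg$t1 - seg$t0)
  }
  # final grid point(s) at/after the last segment end
  tail_sel <- which(is.na(occ[, 1L]))
  for (j in tail_sel) occ[j, ] <- p
  occ[occ < 0 & occ > -1e-9] <- 0
  popen <- rowSums(occ[, scheme$conducting, drop = FALSE])
  structure(list(time = out_time, occupancy = occ,
                 open_probability = popen, used_fallback = used_fallback),
            class = "occupancy_trajectory")
}

#' Macroscopic current predicted by a scheme under a protocol
#'
#' current(t) = N * i * P_open(t). The peak is the extremum of P_open within
#' the first non-rest (stimulation) epoch (model output is noiseless, so no
#' smoothing is applied); the steady state is the mean over the last 5% of
#' that epoch.
#'
#' @param scheme a `kinetic_scheme`.
#' @param protocol a `stimulus_protocol` containing at least one epoch.
#' @param n_channels channel count N >= 1.
#' @param i_single single-channel current (pA), non-zero; negative for
#'   inward current.
#' @param output_interval output grid step (s).
#' @param p0 initial occupancy; defaults to the rest-level steady state.
#' @return list with `time`, `current`, `open_probability`, `peak_popen`,
#'   `ss_popen`, `peak_current`, `iss_over_ipeak`.
#' @export
simulate_response <- function(scheme, protocol, n_channels, i_single,
                              output_interval = 1e-3, p0 = NULL) {
  stopifnot(n_channels >= 1, is_number(i_single), i_single != 0)
  if (length(protocol$epochs) == 0L) {
    stop("protocol has no stimulation epoch")
  }
  traj <- propagate(scheme, protocol, p0 = p0,
                    output_interval = output_interval)
  e <- protocol$epochs[[1L]]
  in_epoch <- traj$time >= e$start - 1e-12 &
    traj$time < e$start + e$duration - 1e-12
  po <- traj$open_probability
  peak <- max(po[in_epoch])
  t_epoch <- traj$time[in_epoch]
  last5 <- t_epoch >= e$start + 0.95 * e$duration
  ss <- mean(po[in_epoch][last5])
  list(time = traj$time, current = n_channels * i_single * po,
       open_probability = po, peak_popen = peak, ss_popen = ss,
       peak_current = n_channels * i_single * peak,
       iss_over_ipeak = if (peak > 0) ss / peak else NA_real_)
}

#' Model-predicted recovery-from-desensitization curve
#'
#' Runs the full paired-pulse protocol from the rest steady state for each
#' interpulse interval and records the ratio of the test-pulse P_open peak
#' to the conditioning-pulse peak.
#'
#' @param scheme a `kinetic_scheme`.
#' @param intervals interpulse intervals (s), positive, sorted.
#' @param conditioning_duration,test_duration,acid_level,rest_level protocol
#'   parameters, defaulting to the standard 1.5 s pH 5 conditioning and
#'   500 ms pH 5 test with pH 8 interpulse.
#' @param output_interval propagation grid step (s).
#' @return a `recovery_curve` (see [recovery_curve()]); points where the
#'   conditioning pulse did not reach a resolved peak carry a warning flag.
#' @export
simulate_recovery_curve <- function(scheme, intervals,
                                    conditioning_duration = 1.5,
                                    test_duration = 0.5,
                                    acid_level = 5, rest_level = 8,
                                    output_interval = NULL) {
  stopifnot(is.numeric(intervals), all(intervals > 0),
            !is.unsorted(intervals))
  fracs <- numeric(length(intervals))
  flagged <- logical(length(intervals))
  for (j in seq_along(intervals)) {
    dt <- output_interval %||% max(min(intervals[j] / 20, 1e-3), 1e-5)
    prot <- paired_pulse_protocol(intervals[j],
                                  conditioning_duration = conditioning_duration,
                                  test_duration = test_duration,
                                  acid_level = acid_level,
                                  rest_level = rest_level,
                                  baseline = 0)
    traj <- propagate(scheme, prot, output_interval = dt)
    cond <- prot$epochs[[1L]]; test <- prot$epochs[[2L]]
    in_cond <- traj$time >= cond$start - 1e-12 &
      traj$time < cond$start + cond$duration - 1e-12
    in_test <- traj$time >= test$start - 1e-12 &
      traj$time < test$start + test$duration - 1e-12
    p_cond <- max(traj$open_probability[in_cond])
    p_test <- max(traj$open_probability[in_test])
    # conditioning too short: open probability still rising at epoch end
    po_cond <- traj$open_probability[in_cond]
    flagged[j] <- which.max(po_cond) >= length(po_cond)
    fracs[j] <- p_test / p_cond
  }
  rc <- recovery_curve(intervals, fracs)
  rc$flagged <- flagged
  rc
}

#' Scan the microscopic recovery rate constant
#'
#' Multiplies the rate of one transition (canonically the desensitized ->
#' closed/resting recovery step) by each factor, at every pH level where the
#' transition has a non-zero rate, then recomputes the model recovery curve,
#' refits the recovery time course, and recomputes Iss/Ipeak during a pH 5
#' application. Used to ask whether accelerating the one-step recovery rate
#' reproduces the fast-and-steep recovery phenotype (it accelerates tau with
#' essentially unchanged slope, and raises the sustained current).
#'
#' @param scheme a `kinetic_scheme`.
#' @param transition character pair `c(from, to)`.
#' @param multipliers positive factors; 1 reproduces the input scheme.
#' @param intervals interpulse intervals for the recovery curves.
#' @param form recovery-fit functional form, see [fit_recovery()].
#' @return data.frame with columns `multiplier`, `tau_rec`, `slope_m`,
#'   `iss_over_ipeak`.
#' @export
scan_recovery_rate <- function(scheme, transition = c("D", "C"),
                               multipliers = c(1, 10, 100),
                               intervals = 10^seq(log10(0.003), log10(30),
                                                  length.out = 12),
                               form = "hh_power") {
  stopifnot(length(transition) == 2L, all(transition %in% scheme$states))
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  if (!any(vapply(scheme$rates, function(Q) Q[transition[1L], transition[2L]] > 0,
                  logical(1)))) {
    stop(sprintf("transition %s->%s has zero rate at every pH",
                 transition[1L], transition[2L]))
  }
  out <- lapply(multipliers, function(mult) {
    sc <- scheme
    sc$rates <- lapply(sc$rates, function(Q) {
      diag(Q) <- 0
      Q[transition[1L], transition[2L]] <-
        Q[transition[1L], transition[2L]] * mult
      diag(Q) <- -rowSums(Q)
      Q
    })
    rc <- simulate_recovery_curve(sc, intervals)
    fit <- fit_recovery(rc, form = form)
    resp <- simulate_response(sc, application_protocol(duration = 1.5,
                                                       baseline = 0.05),
                              n_channels = 1, i_single = -1,
                              output_interval = 5e-4)
    data.frame(multiplier = mult, tau_rec = fit$tau, slope_m = fit$m,
               iss_over_ipeak = resp$iss_over_ipeak)
  })
  do.call(rbind, out)
}
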