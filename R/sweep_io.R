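#' Recording metadata
#'
#' Patch-level metadata attached to every sweep. The holding potential
#' defaults to -60 mV (the standard holding potential for outside-out ASIC
#' recordings); the reversal potential is optional and defaults to 0 mV when
#' converting single-channel current to conductance.
#'
#' @param patch_id character patch identifier.
#' @param holding_potential holding potential (mV).
#' @param sample_interval sample interval (s), > 0.
#' @param reversal_potential reversal potential (mV) or `NA`.
#' @param construct_label channel construct (e.g. `"WT"`, `"L414A"`).
#' @param temperature_note free-text temperature note.
#' @return a `recording_meta` object.
#' @export
recording_meta <- function(patch_id = "patch-1",
                           holding_potential = -60,
                           sample_interval = 1e-4,
                           reversal_potential = NA_real_,
                           construct_label = "WT",
                           temperature_note = NA_character_) {
  stopifnot(is.character(patch_id), length(patch_id) == 1L,
            is_number(holding_potential),
            is_number(sample_interval), sample_interval > 0)
  structure(list(patch_id = patch_id,
                 holding_potential = holding_potential,
                 reversal_potential = reversal_potential,
                 sample_interval = sample_interval,
                 construct_label = construct_label,
                 temperature_note = temperature_note),
            class = "recording_meta")
}

#' A single patch-clamp sweep
#'
#' Current, stimulus (pH command) and time share one uniform grid. Inward
#' currents are negative: "peak" always means the extremum of the
#' baseline-subtracted absolute current.
#'
#' @param time sample times (s), uniform, strictly increasing, length >= 2.
#' @param current current samples (pA).
#' @param stimulus stimulus samples (pH) on the same grid.
#' @param meta a `recording_meta`.
#' @param sweep_index integer position of the sweep within its run.
#' @return a `sweep` object.
#' @export
patch_sweep <- function(time, current, stimulus, meta = recording_meta(),
                  sweep_index = 1L) {
  stopifnot(is.numeric(time), is.numeric(current), is.numeric(stimulus))
  n <- length(time)
  if (n < 2L || length(current) != n || length(stimulus) != n) {
    stop("time, current and stimulus must have equal length >= 2")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt / dt[1L] - 1)) > 1e-6) {
    stop("time grid must be uniform to within 1 part in 1e6")
  }
  stopifnot(inherits(meta, "recording_meta"))
  structure(list(time = time, current = current, stimulus = stimulus,
                 meta = meta, sweep_index = as.integer(sweep_index)),
            class = "sweep")
}

#' A block of sweeps sharing one grid and protocol
#'
#' The unit of fluctuation analysis: a run of 50-200 responses from one
#' patch, recorded under a fixed stimulus protocol.
#'
#' @param sweeps list of `sweep` objects with identical grids.
#' @param protocol the shared `stimulus_protocol`.
#' @return a `sweep_block` object.
#' @export
sweep_block <- function(sweeps, protocol) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1L,
            all(vapply(sweeps, inherits, logical(1), "sweep")),
            inherits(protocol, "stimulus_protocol"))
  n <- length(sweeps[[1L]]$time)
  dt <- sweeps[[1L]]$meta$sample_interval
  for (s in sweeps) {
    if (length(s$time) != n || abs(s$meta$sample_interval - dt) > 1e-12) {
      stop("all sweeps in a block must share length and sample interval")
    }
  }
  structure(list(sweeps = sweeps, protocol = protocol), class = "sweep_block")
}

#' @export
print.sweep_block <- function(x, ...) {
  s1 <- x$sweeps[[1L]]
  cat(sprintf("<sweep_block> %d sweep(s) x %d samples @ %.6g s (%s, %s)\n",
              length(x$sweeps), length(s1$time), s1$meta$sample_interval,
              s1$meta$patch_id, s1$meta$construct_label))
  print(x$protocol)
  invisible(x)
}

n_sweeps <- function(block) length(block$sweeps)

block_current_matrix <- function(block) {
  vapply(block$sweeps, `[[`, numeric(length(block$sweeps[[1L]]$time)),
         "current")
}

#' Write a sweep block to disk
#'
#' Two dialects are supported. `"tsv"` is the human-readable canonical
#' format: `#key=value` metadata lines, then a header row
#' `time_s current_pA_s0 ... current_pA_sK stimulus_pH`, UTF-8, LF line
#' endings. Protocol epochs are stored in `#epoch=` lines as
#' `start,duration,level,label`. `"container"` is a binary (RDS) container
#' holding the block losslessly (bit-exact floats), intended for large runs.
#'
#' @param block a `sweep_block`.
#' @param path output file path.
#' @param format `"tsv"` or `"container"`.
#' @return invisibly, `path`.
#' @export
write_sweep_block <- function(block, path, format = c("tsv", "container")) {
  format <- match.arg(format)
  stopifnot(inherits(block, "sweep_block"))
  if (length(block$sweeps) == 0L) stop("refusing to write an empty block")
  # re-validate through the constructor (catches hand-edited objects)
  block <- sweep_block(block$sweeps, block$protocol)
  for (s in block$sweeps) {
    patch_sweep(s$time, s$current, s$stimulus, s$meta, s$sweep_index)
  }
  if (format == "container") {
    saveRDS(block, path)
    return(invisible(path))
  }
  s1 <- block$sweeps[[1L]]
  meta <- s1$meta
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  wl <- function(...) writeLines(sprintf(...), con, sep = "\n")
  wl("#patch_id=%s", meta$patch_id)
  wl("#holding_mV=%.17g", meta$holding_potential)
  if (!is.na(meta$reversal_potential)) {
    wl("#reversal_mV=%.17g", meta$reversal_potential)
  }
  wl("#sample_interval_s=%.17g", meta$sample_interval)
  wl("#construct=%s", meta$construct_label)
  wl("#sweep_count=%d", length(block$sweeps))
  wl("#rest_level=%.17g", block$protocol$rest_level)
  for (e in block$protocol$epochs) {
    wl("#epoch=%.17g,%.17g,%.17g,%s", e$start, e$duration, e$level, e$label)
  }
  k <- seq_along(block$sweeps) - 1L
  wl(paste(c("time_s", sprintf("current_pA_s%d", k), "stimulus_pH"),
           collapse = "\t"))
  cur <- block_current_matrix(block)
  tab <- cbind(s1$time, cur, s1$stimulus)
  writeLines(apply(tab, 1L, function(r) paste(sprintf("%.17g", r),
                                              collapse = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Read a sweep block from disk
#'
#' @param path file written by [write_sweep_block()].
#' @param format `"tsv"` or `"container"`.
#' @return a `sweep_block`.
#' @export
read_sweep_block <- function(path, format = c("tsv", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "container") {
    block <- readRDS(path)
    if (!inherits(block, "sweep_block")) stop("container does not hold a sweep_block")
    return(block)
  }
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  if (length(meta_lines) == 0L || any(diff(meta_lines) != 1L)) {
    stop("malformed header: '#' metadata lines must lead the file")
  }
  kv <- list()
  epochs <- list()
  for (i in meta_lines) {
    ln <- sub("^#", "", lines[i])
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0L) stop(sprintf("malformed header line %d: '%s'", i, lines[i]))
    key <- substr(ln, 1L, eq - 1L)
    val <- substr(ln, eq + 1L, nchar(ln))
    if (key == "epoch") {
      parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
      if (length(parts) != 4L) {
        stop(sprintf("malformed epoch on line %d: '%s'", i, lines[i]))
      }
      epochs[[length(epochs) + 1L]] <-
        stimulus_epoch(as.numeric(parts[1L]), as.numeric(parts[2L]),
                       as.numeric(parts[3L]), parts[4L])
    } else {
      kv[[key]] <- val
    }
  }
  need <- c("patch_id", "sample_interval_s", "sweep_count", "rest_level")
  miss <- setdiff(need, names(kv))
  if (length(miss)) stop("missing header key(s): ", paste(miss, collapse = ", "))
  body <- lines[-meta_lines]
  body <- body[nzchar(body)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  n_sw <- as.integer(kv$sweep_count)
  if (length(header) != n_sw + 2L) {
    stop(sprintf("header row has %d columns; expected %d (sweep_count=%d)",
                 length(header), n_sw + 2L, n_sw))
  }
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (any(ncols != n_sw + 2L)) {
    bad <- which(ncols != n_sw + 2L)[1L]
    stop(sprintf("ragged row %d: %d columns, expected %d",
                 bad, ncols[bad], n_sw + 2L))
  }
  tab <- matrix(as.numeric(unlist(rows)), ncol = n_sw + 2L, byrow = TRUE)
  if (anyNA(tab)) stop("non-numeric value in data body")
  time <- tab[, 1L]
  stim <- tab[, n_sw + 2L]
  meta <- recording_meta(
    patch_id = kv$patch_id,
    holding_potential = if (!is.null(kv$holding_mV)) as.numeric(kv$holding_mV) else -60,
    sample_interval = as.numeric(kv$sample_interval_s),
    reversal_potential = if (!is.null(kv$reversal_mV)) as.numeric(kv$reversal_mV) else NA_real_,
    construct_label = if (!is.null(kv$construct)) kv$construct else "WT")
  sweeps <- lapply(seq_len(n_sw), function(k) {
    patch_sweep(time, tab[, k + 1L], stim, meta, sweep_index = k)
  })
  sweep_block(sweeps, stimulus_protocol(epochs, as.numeric(kv$rest_level)))
}

#' Segment a stimulus trace into epoch windows
#'
#' Detects contiguous deviations from the rest level on the stimulus
#' (command) channel. A sample is "active" when its deviation from rest
#' exceeds `threshold_fraction` of the largest step amplitude in the trace;
#' active runs shorter than `debounce` samples are treated as glitches and
#' ignored. Windows are half-open index intervals `[start, end)` (1-based)
#' and exactly tile the debounced active samples.
#'
#' @param stimulus numeric stimulus samples.
#' @param rest_level resting stimulus level.
#' @param threshold_fraction fraction of the maximal step amplitude, in
#'   (0, 1); default 0.5.
#' @param debounce minimum run length in samples; default 5.
#' @return data.frame with columns `start`, `end` (half-open, 1-based) and
#'   `level` (median stimulus inside the window); zero rows for a constant
#'   stimulus.
#' @export
segment_epochs <- function(stimulus, rest_level, threshold_fraction = 0.5,
                           debounce = 5L) {
  stopifnot(is.numeric(stimulus), length(stimulus) >= 2L,
            is_number(threshold_fraction),
            threshold_fraction > 0, threshold_fraction < 1)
  dev <- abs(stimulus - rest_level)
  amp <- max(dev)
  empty <- data.frame(start = integer(0), end = integer(0),
                      level = numeric(0))
  if (amp == 0) return(empty)
  active <- dev > threshold_fraction * amp
  r <- rle(active)
  r$values[r$values & r$lengths < debounce] <- FALSE
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  out <- data.frame(start = starts[keep], end = ends[keep] + 1L)
  out$level <- vapply(seq_len(nrow(out)), function(i) {
    stats::median(stimulus[out$start[i]:(out$end[i] - 1L)])
  }, numeric(1))
  out
}
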