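# Fixture builders shared across the suite. Everything is generated in code
# at test time; no stored binary data.

# deterministic open-probability time course of an ASIC-like response:
# fast activation (tau_rise), exponential desensitization (tau_des) to a
# sustained fraction, zero before onset
asic_popen <- function(time, onset = 0.1, p_peak = 0.86, tau_rise = 0.003,
                       tau_des = 0.181, iss_fraction = 0) {
  tt <- time - onset
  p <- ifelse(tt < 0, 0,
              p_peak * (1 - exp(-tt / tau_rise)) *
                (iss_fraction + (1 - iss_fraction) * exp(-pmax(tt, 0) / tau_des)))
  pmin(pmax(p, 0), 1)
}

# a small deterministic sweep block with given per-sweep peak scaling
make_scaled_block <- function(peak_scales, protocol = application_protocol(),
                              dt = 1e-3) {
  time <- seq(0, protocol_end(protocol) + 0.05, by = dt)
  p <- asic_popen(time, onset = protocol$epochs[[1]]$start)
  meta <- recording_meta(sample_interval = dt)
  sweeps <- lapply(seq_along(peak_scales), function(k) {
    patch_sweep(time, -100 * peak_scales[k] * p,
                protocol_to_stimulus(protocol, time), meta, sweep_index = k)
  })
  sweep_block(sweeps, protocol)
}

protocol_end <- asickinetics:::protocol_end
epoch_index_window <- asickinetics:::epoch_index_window

# random irreducible kinetic scheme with k states and two pH levels
random_scheme <- function(k = 4L, levels = c(5, 8)) {
  states <- LETTERS[seq_len(k)]
  rates <- lapply(levels, function(l) {
    Q <- matrix(stats::runif(k * k, 0.1, 20), k, k)
    diag(Q) <- 0
    Q
  })
  names(rates) <- as.character(levels)
  kinetic_scheme(states, conducting = states[k], rates)
}

# tiny synthetic peptide-like structure frame: one GLN residue with
# side-chain atoms at configurable chi1, plus some CA scaffold atoms
make_gln_frame <- function(chi1_deg = 180) {
  # N-CA-CB-CG torsion set to chi1_deg by construction
  th <- chi1_deg * pi / 180
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, 1L, 1L, 1L, 1L, 1L, 1L),
    resname = "GLN",
    atom = c("N", "CA", "CB", "CG", "CD", "OE1", "NE2"),
    element = c("N", "C", "C", "C", "C", "O", "N"))
  # place N at (1,1,0); CA origin; CB along z; CG off-axis rotated by chi1
  coords <- rbind(
    N  = c(1, 0, 1),
    CA = c(0, 0, 0),
    CB = c(0, 0, -1.5),
    CG = c(cos(th) * 1, sin(th) * -1, -2.5),
    CD = c(cos(th) * 2, sin(th) * -2, -3.0),
    OE1 = c(cos(th) * 2.5, sin(th) * -2.5, -2.2),
    NE2 = c(cos(th) * 2.5, sin(th) * -2.5, -4.0))
  structure_frame(atoms, unname(coords))
}

# random globular cloud as a CA-only frame (chain A, residues 1..n)
make_ca_frame <- function(n = 12L, seed = 1L) {
  coords <- asickinetics:::with_seed(seed, matrix(stats::rnorm(n * 3, sd = 4), n, 3L))
  structure_frame(data.frame(chain = "A", resno = seq_len(n),
                             resname = "ALA", atom = "CA", element = "C"),
                  coords)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

random_rotation <- function() {
  A <- matrix(stats::rnorm(9), 3L)
  qr_d <- qr(A)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}
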