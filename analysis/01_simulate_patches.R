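#!/usr/bin/env Rscript
# Generate the synthetic dataset used by the downstream analyses:
#  - per-patch recovery-from-desensitization curves for a wild-type-like
#    condition (tau 0.84 s, m 0.96) and a fast-recovering mutant-like
#    condition (tau 4 ms, m 9), 5 patches each with measurement noise;
#  - a 70-sweep stochastic outside-out patch ensemble for fluctuation
#    analysis at the wild-type operating point (peak P_open 0.86, 10 pS at
#    -60 mV, 100 channels, 350 us solution exchange).
# Raw sweep blocks go to scratch/ (they are large); everything downstream
# needs only the curves and the block, regenerated deterministically from
# the master seed.

suppressPackageStartupMessages(library(asickinetics))
master_seed <- 20260101
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

conditions <- list(
  WT    = list(tau = 0.84, m = 0.96, intervals = recovery_intervals(12)),
  fastA = list(tau = 0.004, m = 9, intervals = recovery_intervals(8, 0.003, 0.1)))

curves <- list()
for (cond in names(conditions)) {
  cf <- conditions[[cond]]
  for (patch in 1:5) {
    rc <- generate_recovery_fractions(
      cf$tau, cf$m, cf$intervals, noise_sd = 0.02,
      seed = derive_seed(master_seed, sprintf("recovery-%s-%d", cond, patch)))
    curves[[length(curves) + 1L]] <-
      data.frame(condition = cond, patch = patch, interval = rc$interval,
                 fraction = rc$fraction)
  }
}
curves <- do.call(rbind, curves)
write.table(curves, "results/recovery_curves.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("wrote %d recovery points (%d patches x 2 conditions)\n",
            nrow(curves), 5L))

# stochastic NSFA ensemble
time <- seq(0, 1.0, by = 1e-4)
prot <- application_protocol(duration = 0.8, baseline = 0.1)
tt <- time - 0.1
popen <- ifelse(tt < 0, 0,
                0.86 * (1 - exp(-tt / 0.003)) * exp(-pmax(tt, 0) / 0.181))
spec <- ensemble_spec(popen = pmin(pmax(popen, 0), 1), n_channels = 100,
                      single_channel_current = -0.6,
                      exchange_time_10_90 = 350e-6)
blk <- generate_nsfa_block(spec, prot, n_sweeps = 70,
                           noise = noise_model(0.3, rundown_per_sweep = 0.001,
                                               rundown_jitter_sd = 0.1),
                           seed = derive_seed(master_seed, "nsfa-ensemble"),
                           time = time,
                           meta = recording_meta(patch_id = "sim-nsfa-1",
                                                 reversal_potential = 0))
write_sweep_block(blk, "scratch/nsfa_block.rds", format = "container")
cat("wrote scratch/nsfa_block.rds:", length(blk$sweeps), "sweeps x",
    length(time), "samples\n")

params <- list(master_seed = master_seed, conditions = conditions,
               nsfa = list(n_sweeps = 70, n_channels = 100,
                           single_channel_current_pA = -0.6,
                           p_open_peak = 0.86, tau_des_s = 0.181,
                           baseline_sd_pA = 0.3, exchange_10_90_s = 350e-6))
writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, pretty = TRUE),
           "results/simulation_parameters.json")
cat("generator parameters recorded in results/simulation_parameters.json\n")
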