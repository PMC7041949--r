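# asickinetics

Quantitative analysis of acid-sensing ion channel (ASIC) gating from
patch-clamp data and kinetic simulations, built around the
desensitization/recovery phenotype of the β11–12 linker (Leu414) of chicken
ASIC1. The package is aimed at channel biophysicists who need a tested,
scriptable replacement for the usual mix of Clampfit/Origin/Matlab steps:
everything from stimulus-epoch segmentation to fluctuation analysis runs
from R, and every estimator is validated against independent oracles.

## What it computes

**Recovery from desensitization.** Paired-pulse protocols (conditioning
acidification, variable interpulse interval *t* at rest pH, test pulse)
yield fraction-recovered curves fit with the Hodgkin–Huxley-type time
course

  I(t) = (1 − e^(−t/τ))^m

with time constant τ and slope *m* (*m* = 1 is mono-exponential; the
stretched-exponential form 1 − e^(−(t/τ)^m) is selectable). Fits are
multi-started so steep recoveries (m ≈ 9–10) do not collapse into
mono-exponential local minima.

**Non-stationary fluctuation analysis (NSFA).** For runs of 50–200
responses from one patch: the longest stretch with peak amplitudes within
10%, robust artifact exclusion, the rundown-resistant successive-trace
variance δ²ᵢ = (Tᵢ₊₁ − Tᵢ)²/2, baseline variance from a 50 ms
pre-application window, binning uniform in current amplitude, and the
current–variance parabola

  σ²(I) = iI − I²/N + σ²_baseline

giving single-channel current *i*, channel count *N*, peak open
probability P_open = |I_peak|/|iN| and conductance g = i/(V_hold − E_rev).

**Markov gating engine.** Kinetic schemes with per-pH rate matrices are
propagated exactly over piecewise-constant pH protocols via spectral
decomposition of Q (matrix-exponential fallback for defective cases). Two
calibrated schemes ship as YAML configs: a linear R↔O↔D topology and a
four-state branching topology (R, protonated-closed C, O, D) in which
desensitization proceeds from shut states. Rate-scan experiments ask how
a one-step change in the microscopic recovery rate maps onto fitted
(τ, m) and sustained current.

**Kinetics and dose–response.** Exponential desensitization decays
(τ_des), 10–90% rise times, Iss/Ipeak sustained-current ratios,
interleaved-reference normalization, and proton dose–response fits
I(pH) = 1/(1 + 10^(n(pH − pH50))).

**Statistics.** Unpaired two-tailed randomization tests (100,000
iterations, add-one p-values) with an exact-enumeration oracle, and
mean ± SEM summaries with n = patches.

**Structure metrics.** PDB/trajectory input (via bio3d), local Kabsch
superposition, RMSD series and two-reference state planes, per-residue
RMSF, χ1–χ3 side-chain dihedrals, and atom-pair distance series — the
metrics used to characterize β11–12 linker mobility in MD trajectories.

**Synthetic data.** Every analysis stage is testable without recordings:
stochastic channel ensembles (exact Gillespie or binomial thinning),
Gaussian baseline noise, multiplicative rundown, and finite solution
exchange (10–90% exchange time, default square steps).

## Worked example

Simulate a 70-sweep outside-out patch at a wild-type-like operating point
(peak P_open 0.86, 10 pS at −60 mV, 100 channels) and recover the
single-channel parameters by NSFA:

```r
library(asickinetics)

time <- seq(0, 1.0, by = 1e-4)                   # 10 kHz grid
prot <- application_protocol(duration = 0.8, baseline = 0.1)  # pH 8 -> 5
tt   <- time - 0.1
p    <- ifelse(tt < 0, 0, 0.86 * (1 - exp(-tt/0.003)) * exp(-pmax(tt,0)/0.181))
spec <- ensemble_spec(popen = p, n_channels = 100, single_channel_current = -0.6)
blk  <- generate_nsfa_block(spec, prot, n_sweeps = 70, noise = noise_model(0.3),
                            seed = 42, time = time,
                            meta = recording_meta(reversal_potential = 0))
nsfa(blk)
#> <nsfa_result> i = -0.595 pA, N = 102, P_open(peak) = 0.847, g = 9.92 pS, baseline 0.091 pA^2
```

The pipeline recovers the generator truth (i = −0.6 pA, N = 100,
P_open 0.86, 10 pS) to within the stochastic scatter of a 70-sweep run.

The numbered scripts under `analysis/` run the full workflow (simulate →
recovery fits → NSFA → kinetic-model scan → dose–response → structure
metrics), printing their findings and writing tables under `results/`.
For example `analysis/02_recovery_fits.R` reports per-condition recovery
parameters and their randomization-test comparison:

```
WT: tau = 0.8621 +/- 0.019 s, m = 0.945 +/- 0.014 (n = 5 patches)
fastA: tau = 0.004228 +/- 9e-05 s, m = 7.98 +/- 0.41 (n = 5 patches)
fold acceleration of recovery: 204
randomization test on tau: p = 0.00754 (exact attainable p = 0.00794)
```

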