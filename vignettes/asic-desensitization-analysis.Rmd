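---
title: "Models and methods: ASIC desensitization kinetics, fluctuation analysis, and structure metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asickinetics)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data tests do and do not establish about real
recordings.

## The biological problem

Acid-sensing ion channels (ASICs) are trimeric sodium channels gated by
extracellular protons. Sustained acidification drives them into a
non-conducting desensitized state; recovery to the activatable resting
state at neutral-to-alkaline pH takes milliseconds to tens of seconds
depending on the residue occupying the β11–12 palm-domain linker
(Leu414 in chicken ASIC1). The package quantifies this cycle from
patch-clamp data: entry kinetics (τ_des), recovery kinetics (τ, m),
open-channel statistics (i, N, P_open, g), proton sensitivity (pH50, n),
and — for molecular-dynamics trajectories — the local conformational
metrics of the linker itself.

## Recovery from desensitization

A paired-pulse protocol measures recovery: a conditioning acidification
(default 1.5 s at pH 5) desensitizes all channels, an interpulse interval
*t* at rest pH (default pH 8) allows partial recovery, and a brief test
pulse (500 ms, pH 5) reads out the recovered fraction as the ratio of
test to conditioning peak. The interval is defined conditioning-end to
test-start. The fraction-recovered curve is fit with

$$I(t) = \left(1 - e^{-t/\tau}\right)^m$$

the classic Hodgkin–Huxley activation form, in which the slope $m$
captures sigmoidicity: $m = 1$ is mono-exponential, and fast-recovering
linker mutants need $m \approx 9$. A rendering ambiguity exists between
this form and the stretched exponential $1 - e^{-(t/\tau)^m}$; because
the Hodgkin–Huxley reading is the natural one for an activation-type
time course, `hh_power` is the default, `stretched_exp` is selectable,
and every round-trip test in the suite runs under both. Within-form
round trips are exact to well under 1%; cross-form fits are never done
silently.

**Fitting.** Nonlinear least squares (Levenberg–Marquardt via
minpack.lm) multi-started over a decade grid of τ spanning the interval
range crossed with $m \in \{0.5, 1, 2, 5, 10\}$; the best-RSS convergent
start wins. Single-start fits demonstrably fall into $m = 1$ local
minima for steep curves — the multi-start grid is what makes the
$m \approx 9$ regime reliable. The asymptote is fixed at 1 as the
functional form dictates; measured fractions may exceed 1 (they are
clipped only at 1.1 in the data model, mirroring that peak ratios can
slightly overshoot on noisy data).

**Aggregation.** Patches are fit individually; parameters are reported
as mean ± SEM with n = patches. Repeats at one interval are averaged
before fitting, unweighted (the repeat count is carried but not used as
a weight — whether the original analyses weighted repeats is unknowable
from the outside, and unweighted is the simpler default).

## Desensitization entry, rise times, sustained current

Decays are fit as $I(t) = c + \sum_k a_k e^{-t/\tau_k}$ (one or two
components; τ_des reports the dominant-amplitude component). The fit
window opens at the first sample after the peak where |I| falls below
95% of the peak — skipping the activation–desensitization cusp — and is
configurable. τ estimates are invariant to current scaling and baseline
offset. The 10–90% rise time interpolates the last 10% and first 90%
crossings linearly between samples; on an exponential rise it equals
τ·ln 9 to 10⁻⁶ on analytic fixtures. Iss/Ipeak averages the last 5% of
the application epoch over the (baseline-subtracted) peak; the 5% window
is a package choice where no standard exists.

## Non-stationary fluctuation analysis

NSFA estimates single-channel current $i$ and channel count $N$ from the
relation between ensemble variance and mean current across the
desensitization relaxation:

$$\sigma^2(I) = iI - \frac{I^2}{N} + \sigma^2_{baseline}$$

Four design points matter.

1. **Successive-trace variance.** The variance is computed per time
   point from successive-sweep differences,
   $\delta_i^2 = (T_{i+1} - T_i)^2 / 2$, averaged over the M − 1 pairs
   (the Heinemann–Conti convention). This cancels slow drift exactly to
   first order: scaling sweep k by (1 + kε) perturbs the estimate only
   at O(ε²), verified numerically in the suite.
2. **Stability filtering.** The longest contiguous run of sweeps whose
   peak amplitudes satisfy max/min ≤ 1.10 is selected (ties to the
   earliest run); "vary by no more than 10%" is interpreted as the
   max/min ratio. Sweeps whose within-sweep successive-difference
   variance is a >5 robust-z outlier (median/MAD, iterated ≤5 passes)
   are excluded as electrical artifacts.
3. **Binning.** Bin edges are uniform in |mean current| between baseline
   and peak, which on an exponential decay produces progressively larger
   time bins while equalizing information per bin. Default 10 bins;
   empty bins are dropped; a peak-to-baseline SNR below 3 is an error.
4. **The fit.** The parabola is linear in (i, 1/N), so the fit is
   ordinary unweighted least squares with the baseline variance held
   fixed at its measured value (a flag frees it). Weighting by bin
   occupancy is not applied; the choice is recorded in the output. When
   the variance is still rising at the largest |I| (P_open < 0.5
   throughout) the vertex is extrapolated and the result carries a
   low-confidence flag; a non-concave fit (N̂ ≤ 0) is an error.

P_open uses the stable-stretch mean peak current; conductance converts as
g [pS] = 1000·i [pA]/(V_hold − E_rev) [mV], with E_rev defaulting to
0 mV (configurable — the reversal potential of the original recordings
is not recoverable, and 0 mV is the conventional assumption for a
sodium-selective channel between physiological-like solutions at
−60 mV).

## The Markov gating engine

Schemes are continuous-time Markov chains with one generator Q per
discrete pH level (the protocols only visit discrete levels; no
continuous proton-binding law is asserted). Occupancies propagate as
$p(t) = p_0 e^{Qt}$ per constant-pH segment via spectral decomposition,
chaining segment-final occupancies, so trajectories are exact at machine
precision rather than ODE-solver accurate. If the eigenvector basis is
defective or its condition number exceeds 10⁸, the engine falls back to
a scaling-and-squaring matrix exponential and flags the result. The
eigen path is validated against the independent `Matrix::expm` oracle to
10⁻⁸ on 1,000 random 3–6-state schemes, with occupancy conservation to
10⁻¹⁰.

**Shipped schemes.** The topology connecting the desensitized state is
itself the scientific question, so two calibrated schemes ship as YAML
configs rather than one guess: `linear` (R↔O↔D, desensitization through
the open state) and the default four-state `branching` (R, protonated-
closed C, O, D; desensitization from the shut state). Both are
calibrated so the pH 5 desensitization τ is ≈0.18 s and the pH 8
recovery τ is ≈0.84 s, the wild-type-like operating point. On the
branching scheme the microscopic recovery rate D→C at pH 5 is set very
small (0.001 s⁻¹) so that the conditioning pulse still desensitizes
completely even when rate-scan experiments accelerate the recovery rate
100-fold; with a larger base value the recovery curve acquires an
instantaneous offset and the fitted slope collapses, which would
confound the question the scan asks (does a one-step acceleration change
the slope?). Model peaks are the global extremum of P_open in the epoch,
unsmoothed — model output is noiseless.

The rate-scan experiment multiplies one transition's rate at every pH
level, recomputes the recovery curve and the sustained current, and
refits (τ, m). On the shipped branching scheme a 100× acceleration
drives τ_rec from 0.84 s to 8.5 ms while m moves by ~4% and Iss/Ipeak
rises ~36-fold — the signature that a simple one-step recovery cannot
produce correlated fast-and-steep recovery curves.

## Synthetic patch data

The generator emulates the features of outside-out patch runs that the
estimators must survive:

- **Channel stochasticity** — either exact event-driven (Gillespie)
  simulation of the aggregated state counts (exponential waiting times,
  pH switching at epoch boundaries, zero-order hold onto the grid), or,
  when a deterministic open-probability course is given, independent
  binomial thinning per sample. The two agree in mean and variance at
  equilibrium within Monte-Carlo error.
- **Baseline noise** — white Gaussian, default 0.3 pA SD. The true
  recording noise is colored by the amplifier's 10 kHz Bessel filter;
  white noise is a deliberate simplification and is flagged as such.
- **Rundown** — multiplicative and cumulative across sweeps with
  optional jitter, matching tachyphylaxis phenomenology. Parameters are
  explicit, never hidden.
- **Solution exchange** — each commanded step becomes an exponential
  relaxation whose 10–90% transit equals the configured exchange time
  (τ_ex = exchange/ln 9); 250–500 µs is the physiological piezo range,
  and 0 returns ideal square steps bit-identically.

Every generator is a pure function of its arguments and a seed; child
seeds derive from (master seed, operation label) so adding a stage never
perturbs existing streams. What passing tests on these data *do* show:
the estimators are unbiased and correctly calibrated under the stated
noise model at realistic sweep counts. What they *cannot* show: robustness
to colored noise, capacitive transients, series-resistance error, or
seal instability — real-data pathologies outside the generator's scope.

## Randomization statistics

Group comparisons use the unpaired two-tailed randomization test on the
absolute difference of group means (the statistic is recorded in the
output so alternatives can be added unambiguously), 100,000 label
reshuffles by default, and the add-one p-value
(n_exceedances + 1)/(n_iterations + 1), which cannot report 0. An exact
enumeration over all label assignments serves as the oracle; sampled and
exact p agree within 3 binomial σ across a randomized small-sample
suite, and the exact test's type-I error at α = 0.05 for n = 5 vs 5
Gaussian nulls falls in [0.035, 0.065]. Note the smallest attainable
exact two-tailed p for 5-vs-5 group-mean permutations is 2/252 ≈ 0.0079;
the package reports the exact attainable bound alongside sampled p so
that headline bounds like "p < 10⁻⁵" can be interpreted against the
resolution the design actually affords.

## Structure metrics

Superposition is the Kabsch SVD solution restricted to proper rotations.
RMSD series superpose each frame on a fit selection and measure over a
measure selection; the default makes them identical — the *local*
alignment appropriate for an ~12-residue linker, where a global fit
would dilute the signal. RMSF aligns frames to the first frame, then
twice to the running mean structure, and reports per-atom fluctuations
about the time-averaged position; the streaming result equals a naive
two-pass recomputation to 10⁻⁹. Whether to superpose locally or on a
larger domain before RMSF is genuinely open; local superposition is the
default and a distinct fit selection provides the alternative. χ
dihedrals use the standard four-atom torsion with the IUPAC sign
convention (validated against a constructed +60° gauche fixture, a dual-
formula oracle, and bio3d). Trajectory input is multi-model PDB or a
plain coordinate table plus topology PDB; native MD binaries are out of
scope — convert upstream. A `stride` argument mirrors the common
practice of analyzing every n-th snapshot.

## Epoch segmentation and file formats

Epochs are detected on the stimulus/command channel: a sample is active
when its deviation from rest exceeds 50% of the largest step amplitude,
and active runs shorter than 5 samples are ignored as glitches. The
threshold and debounce have no external standard; 50%/5 samples are
robust to command-filter ringing. Boundaries are command-based — the
250–500 µs solution-exchange lag is not folded back into the epoch
definition, so time constants much faster than the exchange time should
be interpreted with care. Windows are half-open `[start, end)` in
1-based R indexing.

Sweep blocks serialize either as a self-describing TSV (`#key=value`
header, one current column per sweep — the canonical, diffable fixture
format) or as a lossless binary container for large runs. Kinetic
schemes load from YAML and are re-validated against the generator
invariants (non-negative off-diagonals, zero row sums) on load.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to what
the inference actually needs: recovery and Hill round trips are
noiseless and take milliseconds; NSFA parameter-recovery runs use 70–200
sweeps at 10 kHz over ~1 s sweeps (the regime where per-patch estimates
stabilize); the propagation oracle sweeps 1,000 random schemes; the
type-I calibration uses 2,000 exact 5-vs-5 permutation tests. The full
suite runs in well under a minute on one core. All stochastic stages are
seeded; the interactive analyses under `analysis/` fix one master seed
and derive all child seeds from labeled operations.

## Known limitations

- Single- and double-exponential decays only; no stretched or
  distributed decay models for entry.
- No spectral (stationary) noise analysis and no open-channel excess
  noise term in the variance parabola.
- No voltage dependence in the gating engine; rates are per-pH lookups.
- The fraction-recovered data model tolerates ratios up to 1.1; grossly
  supersaturated curves indicate a measurement problem the package will
  not silently repair.
- PDB parsing inherits bio3d's fixed-column interpretation; mmCIF is not
  supported.
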