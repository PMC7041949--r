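Package: asickinetics
Title: Kinetic, Fluctuation, and Structural Analysis of Acid-Sensing Ion Channel Desensitization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing acid-sensing ion channel (ASIC) gating from
    patch-clamp recordings and simulations. Provides a deterministic Markov
    kinetic-scheme engine (eigen-decomposition propagation over piecewise
    constant pH protocols), a synthetic outside-out patch generator
    (stochastic channel ensembles, baseline noise, rundown, finite solution
    exchange), non-stationary fluctuation analysis with successive-trace
    pairwise variance and current-variance parabola fitting, paired-pulse
    recovery-from-desensitization fitting with a Hodgkin-Huxley slope,
    desensitization decay and pH dose-response (Hill) analysis, unpaired
    two-tailed randomization tests with an exact-enumeration oracle, and
    trajectory structure metrics (Kabsch superposition, RMSD/RMSF,
    side-chain chi dihedrals, atom-pair distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    Matrix,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
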