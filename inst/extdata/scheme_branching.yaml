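# Four-state branching gating scheme: R (resting, unprotonated),
# C (protonated closed), O (open), D (desensitized).
# Desensitization branches off the shut state C, not the open state.
# Rates (1/s) calibrated so that at pH 5 the macroscopic desensitization
# tau is ~0.18 s and at pH 8 recovery from desensitization has tau ~0.84 s,
# with a high (~0.75) peak open probability at pH 5.
states: [R, C, O, D]
conducting: [O]
rates:
  "5":
    R: {C: 500}
    C: {R: 1, O: 350, D: 49}
    O: {C: 50}
    D: {C: 0.001}
  "8":
    R: {C: 0.01}
    C: {R: 500, O: 1, D: 0.01}
    O: {C: 500}
    D: {C: 1.19}
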