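# Three-state linear gating scheme: R (resting) <-> O (open) <-> D
# (desensitized); the desensitized state connects solely to the open state.
# Rates (1/s) chosen to give pH 5 desensitization tau ~0.18 s and pH 8
# recovery tau ~0.84 s, for comparison against the branching topology.
states: [R, O, D]
conducting: [O]
rates:
  "5":
    R: {O: 400}
    O: {R: 10, D: 6.3}
    D: {O: 0.02}
  "8":
    R: {O: 0.01}
    O: {R: 500, D: 0.01}
    D: {O: 1.19}
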