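# Parameter space of the watershed-based nuclei segmentation workflow,
# discretized at p = 20 levels for sensitivity analysis.
#
# Notes:
# - MaxSize / MaxSizeSeg ranges are published as [900, ..., 1500] without a
#   step; this config assumes a step of 100.
# - T1 / T2 (red blood cell thresholds) are declared for design-size
#   fidelity but are consumed by no stage of the bundled simplified
#   pipeline, which has no red-blood-cell removal step.
p: 20
parameters:
  - {name: B,          kind: discrete, low: 210, high: 240, step: 10,  default: 220}
  - {name: G,          kind: discrete, low: 210, high: 240, step: 10,  default: 220}
  - {name: R,          kind: discrete, low: 210, high: 240, step: 10,  default: 220}
  - {name: T1,         kind: discrete, low: 2.5, high: 7.5, step: 0.5, default: 5.0}
  - {name: T2,         kind: discrete, low: 2.5, high: 7.5, step: 0.5, default: 5.0}
  - {name: G1,         kind: discrete, low: 5,   high: 80,  step: 5,   default: 40}
  - {name: G2,         kind: discrete, low: 2,   high: 40,  step: 2,   default: 30}
  - {name: MinSize,    kind: discrete, low: 2,   high: 40,  step: 2,   default: 10}
  - {name: MaxSize,    kind: discrete, low: 900, high: 1500, step: 100, default: 1200}
  - {name: MinSizePl,  kind: discrete, low: 5,   high: 80,  step: 5,   default: 20}
  - {name: MinSizeSeg, kind: discrete, low: 2,   high: 40,  step: 2,   default: 10}
  - {name: MaxSizeSeg, kind: discrete, low: 900, high: 1500, step: 100, default: 1200}
  - {name: FillHoles,  kind: categorical, values: [4-conn, 8-conn], default: 8-conn}
  - {name: MorphRecon, kind: categorical, values: [4-conn, 8-conn], default: 8-conn}
  - {name: Watershed,  kind: categorical, values: [4-conn, 8-conn], default: 8-conn}
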