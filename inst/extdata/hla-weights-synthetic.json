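{
  "description": "SYNTHETIC HLA class II weights for the T1DGRS engine. The published genotype-interaction weights live in supplementary material of the source scores and are not redistributed here; these values preserve the qualitative structure (DR3-DQ2/DR4-DQ8 synergy, DR15-DQ6 protective floor at 0, neutral X baseline 0) on a log-odds-like scale. All weights are nonnegative so normalized scores stay in [0,1].",
  "additive": {
    "DR3-DQ2": 1.0,
    "DR4-DQ8": 1.2,
    "DR15-DQ6": 0.0,
    "X": 0.0
  },
  "pairs": {
    "DR3-DQ2|DR4-DQ8": 3.0,
    "DR3-DQ2|DR3-DQ2": 2.2,
    "DR4-DQ8|DR4-DQ8": 2.6
  }
}
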