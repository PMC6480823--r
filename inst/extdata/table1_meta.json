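{
  "n": 219,
  "types": {
    "NS1": "continuous", "NS2": "continuous",
    "AN1": "continuous", "AN2": "continuous",
    "UN1": "continuous", "UN2": "continuous",
    "Math": "ordinal", "Eng": "ordinal"
  },
  "grade_proportions": {
    "Math": [0.123, 0.311, 0.297, 0.174, 0.096],
    "Eng": [0.059, 0.393, 0.338, 0.174, 0.037]
  },
  "note": "Printed summary of the bundled empirical example: Pearson correlations among six intelligence test halves (variances on the diagonal), polyserial correlations with two ordinal grades, one polychoric grade-grade correlation; lower triangle, n = 219."
}
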