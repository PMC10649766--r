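{
  "term_labels": ["A", "B", "C", "D", "E", "F", "G",
    "AxB", "AxC", "AxD", "AxE", "AxF", "AxG",
    "BxC", "BxD", "BxE", "BxF", "BxG",
    "CxD", "CxE", "CxF", "CxG",
    "DxE", "DxF", "DxG",
    "ExF", "ExG",
    "FxG",
    "Constant"],
  "coefficients": [0.165404, -0.626781, -0.43888, -0.181944, 0.231918,
    0.34817, -0.37727,
    -0.578918, 0.131548, 0.255888, -0.035711, 0.255385, -0.358334,
    1.366192, 0.127896, -1.453575, -0.291472, 0.19813,
    0.372922, 0.437779, -0.661009, 0.734438,
    0.068061, -0.678175, 0.10932,
    0.417461, -0.803023,
    -0.590657,
    -0.419399],
  "bounds": {
    "factor": ["age", "kvp", "bsa", "hr", "co", "cm", "dtt",
      "cta_la_over_400"],
    "min": [24, 70, 1.27, 45, 4.18, 17.0, 2.00, 0.61],
    "max": [90, 140, 2.70, 139, 11.11, 75.0, 5.13, 2.17]
  },
  "target_cta": 400,
  "diagnostics": null,
  "metadata": {
    "description": "Published reference coefficient set for the 29-term head-and-neck CTA formula, with the derivation cohort's scaling bounds (n = 450).",
    "n": 450
  }
}
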