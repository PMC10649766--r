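# Verification-cohort marginals (112-patient group). Sampling uses this
# cohort's own ranges, but the scaling bounds are the derivation
# cohort's: verification patients are evaluated under the trained
# model's normalization, and their ranges are nearly but not exactly
# nested in the derivation ranges.
"n": 112
residual_sd: 0.084
ground_truth: table3
factors:
  age:  {mean: 55.0,  sd: 13.9,  min: 31.0,  max: 88.0}
  kvp:  {mean: 118.4, sd: 5.5,   min: 100.0, max: 120.0,
         levels: [100, 120]}
  bsa:  {mean: 1.81,  sd: 0.19,  min: 1.25,  max: 2.39}
  hr:   {mean: 72.3,  sd: 12.2,  min: 45.0,  max: 103.0}
  co:   {mean: 6.45,  sd: 0.77,  min: 4.5,   max: 9.6}
  cm:   {mean: 54.4,  sd: 8.9,   min: 32.0,  max: 68.0}
  dtt:  {mean: 3.86,  sd: 0.32,  min: 2.37,  max: 4.61}
scaling:
  age:  {min: 24.0,  max: 90.0}
  kvp:  {min: 70.0,  max: 140.0}
  bsa:  {min: 1.27,  max: 2.70}
  hr:   {min: 45.0,  max: 139.0}
  co:   {min: 4.18,  max: 11.11}
  cm:   {min: 17.0,  max: 75.0}
  dtt:  {min: 2.00,  max: 5.13}
  cta_la_over_400: {min: 0.61, max: 2.17}
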