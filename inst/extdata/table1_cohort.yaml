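# Derivation-cohort marginals (450-patient head-and-neck CTA group).
# Factors are sampled as independent truncated normals; tube voltage is
# snapped to the clinical step set after the draw.
"n": 450
residual_sd: 0.084
ground_truth: table3
factors:
  age:  {mean: 56.0,  sd: 13.3,  min: 24.0,  max: 90.0}
  kvp:  {mean: 100.0, sd: 19.0,  min: 70.0,  max: 140.0,
         levels: [70, 80, 100, 120, 140]}
  bsa:  {mean: 1.75,  sd: 0.20,  min: 1.27,  max: 2.70}
  hr:   {mean: 72.1,  sd: 12.8,  min: 45.0,  max: 139.0}
  co:   {mean: 6.32,  sd: 1.06,  min: 4.18,  max: 11.11}
  cm:   {mean: 36.7,  sd: 11.5,  min: 17.0,  max: 75.0}
  dtt:  {mean: 3.08,  sd: 0.53,  min: 2.00,  max: 5.13}
# Scaling bounds used for normalization and response denormalization;
# for the derivation cohort these equal the marginal ranges. The
# response scale is the CTA number of LA divided by 400.
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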