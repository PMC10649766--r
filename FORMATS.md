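# File formats

All files are plain text; CSVs are RFC-4180 with a mandatory header.

## Patient tables (CSV)

Input to `fit`, `predict`, `verify`, `plan-dose`; output of `simulate`.

| column       | units     | required                                  |
|--------------|-----------|-------------------------------------------|
| `patient_id` | —         | optional (generated as `P0001`… if absent) |
| `age`        | yr        | yes                                        |
| `kvp`        | kVp       | yes                                        |
| `bsa`        | m²        | yes                                        |
| `hr`         | beats/min | yes                                        |
| `co`         | L/min     | yes                                        |
| `cm`         | c.c.      | yes, except for dose planning              |
| `dtt`        | s         | yes                                        |
| `cta_la`     | CTA units | required by `fit` and `verify`             |

All factor readings must be finite and strictly positive; violations
are reported with their row numbers.

## Model artifacts (JSON)

Written by `write_model()` / the `fit` subcommand, read by
`read_model()`. Fields:

- `term_labels` — the canonical 29-term order (`A`…`G`, `AxB`…`FxG`,
  `Constant`); files that disagree are rejected at load.
- `coefficients` — 29 numbers in that order, serialized with 17
  significant digits (lossless round trip).
- `bounds` — parallel arrays `factor` / `min` / `max` over the seven
  factors plus `cta_la_over_400` (the response scale).
- `target_cta` — raw CTA target for dose planning (default 400).
- `diagnostics` — optional: `loss_phi`, `variance`, `r`, `n`, `rank`.
- `metadata` — free-form provenance (seed, n, description, …).

The packaged reference artifact is
`inst/extdata/table3_model.json`.

## Cohort specs (YAML)

Input to `simulate` / `read_cohort_spec()`. Keys:

- `n` — default cohort size (quoted `"n"`, since bare `n` is a YAML
  boolean).
- `residual_sd` — Gaussian noise SD on the normalized response scale.
- `ground_truth` — `table3` (the packaged coefficients) or an explicit
  list of 29 numbers.
- `factors.<id>` — `mean`, `sd`, `min`, `max` in raw units, optional
  `levels` (discrete settings the draw is snapped to).
- `scaling.<id>` — `min`/`max` normalization bounds per factor and for
  `cta_la_over_400`.

Packaged specs: `table1_cohort.yaml` (derivation marginals, n = 450)
and `table4_cohort.yaml` (verification marginals, n = 112).

## Dose plans (CSV)

Output of `plan-dose` / `plan_cohort()`: `patient_id`, `cm_min`,
`cm_max` (c.c.; the model's dose extremes), `v8_at_cm_min`,
`v8_at_cm_max` (predicted raw CTA numbers at those extremes),
`target_cta`, `cm_expect` (recommended dose, c.c.), `achievable`,
`clipped`, `error` (empty for successful plans).

## Agreement output

Per-patient CSV: `patient_id`, `actual`, `predicted`, `at_percent`.
JSON summary: `n`, `at_avg`, `at_sd` (percent), `bins` (2%-wide
histogram: `bin_lo`, `bin_hi`, `count`).
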