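# Anopheles gambiae thermal life-history preset (editable).
# Simplified per-stage transcription in the style of published thermal-trait
# fits for this species; narrower thermal niche than Ae. aegypti.
name: anopheles_gambiae
mort_floor: 1.0e-6
development:
  egg:   {form: briere, params: {a: 2.50e-4, T_min: 14.0, T_max: 38.0}}
  larva: {form: briere, params: {a: 9.00e-5, T_min: 14.0, T_max: 37.0}}
  pupa:  {form: briere, params: {a: 2.60e-4, T_min: 14.0, T_max: 38.5}}
mortality:
  egg:   {form: constant, params: {rate: 0.06}}
  larva: {form: constant, params: {rate: 0.10}}
  pupa:  {form: constant, params: {rate: 0.06}}
  adult: {form: linear, params: {intercept: 0.035, slope: 0.0028}, floor: 0.03}
fecundity:
  form: quadratic
  params: {c: 0.095, T_min: 16.0, T_max: 36.0}
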