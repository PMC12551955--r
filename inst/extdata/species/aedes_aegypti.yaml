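# Aedes aegypti thermal life-history preset (editable).
# Simplified per-stage transcription in the style of published thermal-trait
# fits for this species: Briere development and fecundity, linear adult
# mortality, constant juvenile mortalities. Units: rates per day, T in °C.
name: aedes_aegypti
mort_floor: 1.0e-6
development:
  egg:   {form: briere, params: {a: 2.13e-4, T_min: 13.35, T_max: 40.08}}
  larva: {form: briere, params: {a: 1.10e-4, T_min: 11.36, T_max: 39.17}}
  pupa:  {form: briere, params: {a: 3.00e-4, T_min: 11.36, T_max: 39.67}}
mortality:
  egg:   {form: constant, params: {rate: 0.05}}
  larva: {form: constant, params: {rate: 0.08}}
  pupa:  {form: constant, params: {rate: 0.05}}
  adult: {form: linear, params: {intercept: 0.020, slope: 0.0030}, floor: 0.02}
fecundity:
  # eggs per female per day; peak ~8 near 29 °C
  form: briere
  params: {a: 8.0e-3, T_min: 14.58, T_max: 34.61}
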