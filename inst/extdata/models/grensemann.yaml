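model_id: grensemann
label: Grensemann et al.
population_class: crrt
n_compartments: 2
parametrization: clv
thetas:
  cl: 5.06
  v1: 8.31
  q: 8.0
  v2: 20.0
theta_provenance:
  cl: printed
  v1: printed
  q: placeholder
  v2: placeholder
iiv_cv:
  cl: 29.8
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: []
reference: {}
notes: >
  No covariate formulas printed; typical CL 5.06 L/h and V1 8.31 L used as
  constants, Q/V2 placeholders. IIV on CL only.
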