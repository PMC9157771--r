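model_id: li
label: Li et al.
population_class: mixed
n_compartments: 2
parametrization: clv
thetas:
  cl: 14.6
  clcr_exp: 0.62
  age_exp: -0.34
  v1: 10.8
  wt_exp: 0.99
  q: 18.6
  v2: 12.6
theta_provenance:
  cl: printed
  clcr_exp: printed
  age_exp: printed
  v1: printed
  wt_exp: printed
  q: printed
  v2: printed
iiv_cv:
  cl: 34.3
  v1: 31.94
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [clcr, age, weight]
reference:
  covariates:
    clcr: 83
    age: 35
    weight: 70
  typical:
    cl: 14.6
    v1: 10.8
notes: >
  CL (L/h) = 14.6 x (CLcr/83)^0.62 x (AGE/35)^-0.34;
  Vc (L) = 10.8 x (WT/70)^0.99; Q = 18.6 L/h; Vp = 12.6 L.
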