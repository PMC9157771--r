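model_id: muro
label: Muro et al.
population_class: mixed
n_compartments: 1
parametrization: clv
thetas:
  cl: 11.1
  v1: 33.6
  mscr_ref: 0.7
theta_provenance:
  cl: printed
  v1: printed
  mscr_ref: printed
iiv_cv:
  cl: 52.1
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [scr]
reference:
  covariates:
    mscr: 0.7
  typical:
    cl: 11.1
    v1: 33.6
notes: >
  CL (L/h) = 11.1 x (mSCR/0.7)^-1 with mSCR the serum creatinine in mg/dL
  floored at 0.4 mg/dL. No interindividual variability reported on V.
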