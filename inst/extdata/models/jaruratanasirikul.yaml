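model_id: jaruratanasirikul
label: Jaruratanasirikul et al.
population_class: mixed
n_compartments: 1
parametrization: clv
thetas:
  cl_intercept: 1.505
  cl_slope: 0.0301
  v1: 23.7
theta_provenance:
  cl_intercept: placeholder
  cl_slope: placeholder
  v1: printed
iiv_cv:
  cl: 48.0
  v1: 35.0
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [age, scr, sex]
reference: {}
notes: >
  TVCL = theta1 + theta2 x MDRD-CLcr; the two thetas are not printed, the
  placeholders reproduce the printed typical CL 3.01 L/h at an MDRD clearance
  of 50 ml/min/1.73 m^2. V = 23.7 L.
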