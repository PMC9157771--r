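model_id: onichimowski
label: Onichimowski et al.
population_class: crrt
n_compartments: 2
parametrization: clv
thetas:
  cl: 15.1
  v1: 27.9
  alb_exp: -2.87
  alb_ref: 24.6
  q: 10.0
  v2: 15.0
theta_provenance:
  cl: printed
  v1: printed
  alb_exp: printed
  alb_ref: printed
  q: placeholder
  v2: placeholder
iiv_cv:
  cl: 43.7
  v1: 53.1
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [albumin]
reference: {}
notes: >
  V1 (L) = 27.9 x (ALB/24.6)^-2.87 with albumin in g/L; CL fixed at the
  typical 15.1 L/h (no clearance covariate printed). Q and V2 placeholders.
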