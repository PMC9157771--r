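model_id: ulldemolins
label: Ulldemolins et al.
population_class: crrt
n_compartments: 1
parametrization: clv
thetas:
  cl: 3.68
  diuresis_slope: 0.22
  v1: 33.0
  wt_exp: 2.07
theta_provenance:
  cl: printed
  diuresis_slope: printed
  v1: printed
  wt_exp: printed
iiv_cv:
  cl: 37.0
  v1: 45.0
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [residual_diuresis, weight]
reference:
  covariates:
    residual_diuresis: 0
    weight: 73
  typical:
    v1: 33.0
notes: >
  CL (L/h) = theta_CL + 0.22 x (residual diuresis [ml/day] / 100);
  V (L) = 33.0 x (WT/73)^2.07. The printed CL 3.68 L/h is taken as theta_CL,
  i.e. the zero-diuresis value (assumption flagged: the source table does not
  state the reference diuresis).
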