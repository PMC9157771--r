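model_id: mattioli
label: Mattioli et al.
population_class: non_crrt
n_compartments: 1
parametrization: clv
thetas:
  cl: 2.181
  sepsis_effect: -0.2
  male_effect: 0.2
  v1: 8.305
  alb_exp: -1.0
  age_exp: 0.5
  alb_ref: 22.0
  age_ref: 61.0
theta_provenance:
  cl: printed
  sepsis_effect: placeholder
  male_effect: placeholder
  v1: printed
  alb_exp: placeholder
  age_exp: placeholder
  alb_ref: printed
  age_ref: printed
iiv_cv:
  cl: 44.38
  v1: 66.48
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [sepsis, sex, albumin, age]
reference: {}
notes: >
  CL = 2.181 x (1 + theta4 x sepsis) x (1 + theta6 x male);
  V = 8.305 x (ALB/22)^theta3 x (AGE/61)^theta5. The covariate effect
  magnitudes, signs and exponents are not printed; the stored values are
  placeholders (sepsis lowering CL by 20%, male sex raising it by 20%,
  V decreasing with albumin, increasing with age).
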