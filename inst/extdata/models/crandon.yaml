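model_id: crandon
label: Crandon et al.
population_class: non_crrt
n_compartments: 2
parametrization: micro
thetas:
  k10_intercept: 0.3922
  k10_slope: 0.0025
  v1_per_kg: 0.239
  k12: 0.25
  k21: 0.50
theta_provenance:
  k10_intercept: printed
  k10_slope: printed
  v1_per_kg: printed
  k12: placeholder
  k21: placeholder
iiv_cv:
  v1: 53.76
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [clcr, weight, height, sex]
reference:
  covariates:
    clcr: 0
  typical:
    k10: 0.3922
notes: >
  Micro-constant parametrization: K10 (1/h) = 0.3922 + 0.0025 x CLcr;
  V1 (L) = AdjBW (kg) x 0.239 L/kg. Peripheral-compartment constants are not
  printed; k12/k21 stored here are placeholders. IIV is reported on V1 only,
  so individual CL = K10 x V1 inherits the V1 random effect.
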