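model_id: dhaese
label: Dhaese et al.
population_class: non_crrt
n_compartments: 1
parametrization: clv
thetas:
  cl: 9.46
  clcr_ref: 135.0
  v1: 48.1
theta_provenance:
  cl: printed
  clcr_ref: printed
  v1: printed
iiv_cv:
  cl: 37.5
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [clcr]
reference:
  covariates:
    clcr: 135
  typical:
    cl: 9.46
    v1: 48.1
notes: >
  CL (L/h) = 9.46 x (CG-CLcr/135); V = 48.1 L; no IIV reported on V.
  Developed on continuous-infusion data.
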