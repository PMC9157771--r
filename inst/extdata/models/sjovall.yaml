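model_id: sjovall
label: Sjovall et al.
population_class: non_crrt
n_compartments: 2
parametrization: clv
thetas:
  tvcl: 0.663
  clcr_slope: 0.083
  v1: 16.916
  q: 10.0
  v2: 12.0
theta_provenance:
  tvcl: placeholder
  clcr_slope: printed
  v1: printed
  q: placeholder
  v2: placeholder
iiv_cv:
  cl: 40.578
  v1: 38.872
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [clcr]
reference: {}
notes: >
  CL = TVCL x [2 + (CLcr x 0.083)]. The printed typical CL of 6.83 L/h
  cannot be reproduced at any obvious reference CLcr from the formula as
  printed; TVCL is stored as the placeholder 0.663, which returns 6.83 L/h
  at CLcr 100 ml/min. Excluded from formula-fidelity checks.
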