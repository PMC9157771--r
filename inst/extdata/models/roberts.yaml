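model_id: roberts
label: Roberts et al.
population_class: non_crrt
n_compartments: 2
parametrization: clv
thetas:
  cl_slope: 0.136
  v1: 7.9
  q: 10.5
  v2: 12.0
theta_provenance:
  cl_slope: placeholder
  v1: printed
  q: placeholder
  v2: placeholder
iiv_cv:
  cl: 15.3
  v1: 44.7
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [clcr]
reference: {}
notes: >
  TVCL (L/h) = theta1 x CLcr (Cockcroft-Gault). theta1 is not printed; the
  placeholder 0.136 reproduces the printed typical CL 13.6 L/h at CLcr
  100 ml/min. Q and V2 are placeholders.
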