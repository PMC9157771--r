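model_id: padulles
label: Padulles et al.
population_class: crrt
n_compartments: 2
parametrization: clv
thetas:
  fr_slope: 0.702
  v1: 24.9
  v2: 283.0
  q: 6.49
theta_provenance:
  fr_slope: printed
  v1: printed
  v2: printed
  q: printed
iiv_cv:
  cl: 50.79
  v1: 45.7
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [crrt_flow]
reference: {}
notes: >
  CL (L/h) = 0.702 x FR with FR the summed dialysate + ultrafiltrate flow in
  L/h; Vc = 24.9 L, Vp = 283 L, distributional CL 6.49 L/h. The printed
  typical CL of 7.78 L/h implies FR near 11 L/h, far above routine CRRT
  effluent flows (1.5-3.5 L/h); the formula is applied as printed, so
  clearances on typical effluent settings are much lower than 7.78 L/h.
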