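model_id: burger
label: Burger et al.
population_class: mixed
n_compartments: 2
parametrization: clv
thetas:
  cl_res: 3.2
  sieving: 0.8
  cl_nocrrt: 5.9
  clcr_slope: 0.0071
  median_clcr: 50.0
  vc_coef: 27.2
  vc_typical: 17.0
  median_bw: 70.0
  q: 14.0
  v2: 15.0
theta_provenance:
  cl_res: printed
  sieving: placeholder
  cl_nocrrt: printed
  clcr_slope: printed
  median_clcr: placeholder
  vc_coef: printed
  vc_typical: printed
  median_bw: placeholder
  q: printed
  v2: printed
iiv_cv:
  cl: 40.0
  v1: 51.0
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [crrt, crrt_flow, clcr, weight]
reference: {}
notes: >
  CRRT patients: CL (L/h) = 3.2 + Sc x Q_FD; the sieving coefficient is not
  printed, the placeholder Sc = 0.8 with a typical filtrate-dialysate flow of
  2 L/h reproduces the printed CRRT clearance of 4.8 L/h. Non-CRRT patients:
  CL (L/h) = 5.9 x [1 + 0.0071 x (CLcr - median CLcr)] with a placeholder
  median CLcr of 50 ml/min. Vc as printed is 16 x (BW/medianBW) x 1.7 =
  27.2 L at the median weight, while the table lists a typical V of 17.0 L;
  both readings are stored (vc_coef / vc_typical) and the printed formula is
  the default. Placeholder median BW 70 kg.
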