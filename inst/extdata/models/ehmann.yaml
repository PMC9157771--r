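model_id: ehmann
label: Ehmann et al.
population_class: non_crrt
n_compartments: 2
parametrization: clv
thetas:
  cl: 9.25
  clcr_slope: 0.00977
  clcr_ref: 80.8
  clcr_inflection: 143.0
  v1: 7.89
  wt_exp: 0.945
  v2: 12.0
  alb_slope: 0.202
  alb_ref: 2.79
  q: 28.4
theta_provenance:
  cl: printed
  clcr_slope: printed
  clcr_ref: printed
  clcr_inflection: placeholder
  v1: printed
  wt_exp: printed
  v2: placeholder
  alb_slope: printed
  alb_ref: printed
  q: printed
iiv_cv:
  cl: 27.1
  v1: 31.5
sigma:
  kind: proportional
  prop: 0.2
  add: 0.0
  provenance: placeholder
required_covariates: [clcr, weight, albumin]
reference:
  covariates:
    clcr: 80.8
    weight: 70
  typical:
    cl: 9.25
    v1: 7.89
notes: >
  Below the CLcr inflection point: CL (L/h) = 9.25 x [1 + 0.00977 x
  (CLcr_CG - 80.8)]; above it CL is held at the inflection value. The
  inflection point and theta_V2 are not printed in the summary table; the
  values stored here are placeholders. V2 (L) = theta_V2 x [1 - 0.202 x
  (ALB[g/dL] - 2.79)]; Q = 28.4 L/h.
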