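preset: paper_default
cohort_size: 140
seed: 20260113
age_mean: 23.600000000000001
age_sd: 3.8
age_bounds:
- 18.0
- 35.0
p_female: 0.5
diet_probs:
- 0.35
- 0.45
- 0.2
density:
  mean: 185.0
  sd: 28.0
  lower: 150.0
  upper: 220.0
exposure:
  p_nonuser: 0.176545
  shape: 2.76088
  scale: 0.468213
  cap: 5.0
likert:
  n_domains: 3
  items_per_domain: 3
  levels: 5
  item_corr: 0.132481
  thresholds:
  - -0.357158
  - 0.642842
  - 1.49284
  - 2.39284
oxload:
  alpha_x: 1.0
  alpha_sex: 1.07513
  alpha_diet: 0.147836
  sigma_eps: 1.45008
outcomes:
  beta_D: 20.045200000000001
  beta_S: 0.442008
  sigma_eta: 13.565099999999999
  sigma_upsilon: 0.148121
category_cuts:
- 0.5
- 1.5
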