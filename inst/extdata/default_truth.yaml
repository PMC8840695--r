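theta1:
  (Intercept): 2.547221847859
  age_group20-39: 0.226
  age_group6-19: -0.829
  feverNo: 0.153
  diarrhoeaNo: -0.227
  birth_weight>=2500 g: -1.248
  residenceRural: -0.653
  wealthMiddle: 1.065
  wealthPoorer: 1.253
  educationPrimary: -1.473
  educationPost primary: -1.841
theta2:
  (Intercept): 1.208407334614
  age_group20-39: 0.531
  age_group6-19: 0.096
  feverNo: -0.712
  diarrhoeaNo: -0.496
  birth_weight>=2500 g: 0.038
  residenceRural: 0.102
  wealthMiddle: 0.224
  wealthPoorer: 0.282
  educationPrimary: -0.772
  educationPost primary: -0.519
sigma:
  sigma11: 0.104
  sigma22: 0.314
  sigma12: 0.180709711969
n_clusters: 400
mean_children: 8.0
seed: 1
marginals:
  age_group:
    40-59: 0.28
    20-39: 0.32
    6-19: 0.4
  sex:
    Male: 0.46
    Female: 0.54
  fever:
    'Yes': 0.17
    'No': 0.83
  diarrhoea:
    'Yes': 0.13
    'No': 0.87
  cough:
    'Yes': 0.3
    'No': 0.7
  birth_weight:
    <2500 g: 0.09
    '>=2500 g': 0.91
  residence:
    Urban: 0.28
    Rural: 0.72
  wealth:
    Richer: 0.365
    Middle: 0.21
    Poorer: 0.425
  education:
    No education: 0.012
    Primary: 0.46
    Post primary: 0.528
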