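'n': 1697
seed: 1
age_params:
  mean: 48.353
  sd: 15.209
  min: 18.0
  max: 90.0
duration_params:
  shape: 1.047
  scale: 18.908
  min_age_at_onset: 16.0
sex_p: 0.731
phenotype_probs:
  CIS: 0.041
  PPMS: 0.106
  RRMS: 0.684
  SPMS: 0.161
  unclear: 0.008
severity_loadings:
  duration: 0.03
  duration_center: 12.0
  phenotype:
    CIS: -0.8
    PPMS: 0.9
    RRMS: -0.2
    SPMS: 1.0
    unclear: 0.0
  noise_sd: 1.0
symptom_params:
  symptom:
  - balance
  - bladder
  - depression
  - fatigue
  - gait
  - gastrointestinal
  - memory
  - pain
  - paresthesia
  - spasms
  - tremors
  - muscle_weakness
  prevalence:
  - 0.357
  - 0.291
  - 0.127
  - 0.543
  - 0.35
  - 0.229
  - 0.219
  - 0.297
  - 0.441
  - 0.292
  - 0.105
  - 0.324
  slope:
  - 1.4
  - 1.3
  - 1.6
  - 1.3
  - 1.6
  - 1.3
  - 1.2
  - 1.3
  - 0.9
  - 1.5
  - 1.5
  - 1.5
srdss_probs:
  0-3.5: 0.703
  4-6.5: 0.206
  '>=7': 0.091
covariate_effects:
  eq5d:
    severity: -0.55
    depression: -0.5
    pain: -0.35
    muscle_weakness: -0.3
    memory: -0.3
    fatigue: -0.25
    benefit_receives: -0.2
    age_per_decade: -0.1
  vas_scale: 0.8
residual_rho: 0.55
eq5d_marginal:
  probs:
  - 0.0
  - 0.02
  - 0.061
  - 0.123
  - 0.184
  - 0.25
  - 0.37
  - 0.5
  - 0.62
  - 0.75
  - 0.81
  - 0.865
  values:
  - 5.0
  - 25.0
  - 43.2
  - 61.5
  - 78.2
  - 80.0
  - 86.2
  - 90.7
  - 94.5
  - 96.2
  - 96.7
  - 99.9
  ceiling_mass: 0.135
vas_marginal:
  probs:
  - 0.0
  - 0.03
  - 0.0615
  - 0.123
  - 0.1845
  - 0.25
  - 0.375
  - 0.5
  - 0.625
  - 0.75
  - 0.8125
  - 0.875
  - 0.9375
  - 1.0
  values:
  - 0.0
  - 20.0
  - 32.0
  - 40.0
  - 50.0
  - 60.0
  - 70.0
  - 80.0
  - 85.0
  - 90.0
  - 90.0
  - 95.0
  - 99.0
  - 100.0
social_params:
  benefit:
    p_receives: 0.336
    slope_receives: 1.1
    p_applied: 0.062
    slope_applied: 0.8
  employment:
    p: 0.609
    slope: -0.9
  dmt:
    probs:
      monoclonal: 0.197
      injectable: 0.138
      other: 0.018
      none: 0.311
      oral: 0.336
    slopes:
      monoclonal: 0.35
      injectable: -0.45
      other: 0.2
      none: 0.05
      oral: 0.0
  citizen_p: 0.895
  education_probs:
    mandatory: 0.038
    apprenticeship: 0.405
    highschool: 0.092
    higher_professional: 0.146
    university: 0.275
    other_or_unknown: 0.044
  living_probs:
    clinic_nursing_home: 0.004
    with_family: 0.296
    with_friends_relatives: 0.026
    alone: 0.219
    with_parents: 0.021
    with_partner: 0.411
    other_or_unknown: 0.023
  marital_probs:
    divorced: 0.109
    married: 0.502
    registered_partnership: 0.021
    separated: 0.024
    unmarried: 0.302
    widowed: 0.027
    unknown: 0.015
  smoking_probs:
    never: 0.437
    past: 0.215
    current: 0.348
  family_ms_p: 0.141
  first_symptom:
    visual_p: 0.401
    paresthesia_p: 0.589
    gait_p: 0.31
    gait_slope: 0.45
    spasms_p: 0.084
  comorbidity:
    p:
      mononucleosis: 0.145
      hypertension: 0.129
      cancer: 0.026
      diabetes1: 0.004
      diabetes2: 0.016
      cardiovascular: 0.04
    slopes:
      mononucleosis: 0.0
      hypertension: 0.15
      cancer: 0.0
      diabetes1: 0.0
      diabetes2: 0.35
      cardiovascular: 0.25
  bmi:
    meanlog: 3.182
    sdlog: 0.181
    severity_slope: 0.022
missingness:
  phenotype: 0.005
  living_situation: 0.013
  marital_status: 0.015
  education: 0.01
  smoking: 0.006
  bmi: 0.033
msss_fraction: 0.552150854449
edss_params:
  intercept: 2.6
  slope: 1.7
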