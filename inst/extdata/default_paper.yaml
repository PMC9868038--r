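# Default generator configuration for the synthetic osteoporotic-fracture
# claims cohort. Marginal rates, the MPR decile histogram, regimen mixes and
# the treatment log-odds are calibrated to the published hospital-database
# study this package emulates. Categorical mixes are renormalized exactly to
# 1 at load time (printed percentages carry rounding error).
n_patients: 1000
seed: 20160201
index_year: 2017
study_window: [-730, 730]

cohort_mix:
  hip: 0.5039
  vertebrae: 0.2376
  nvnh: 0.2585

covariate_marginals:
  age_band: {"50-59": 0.050, "60-69": 0.126, "70-79": 0.230, "80-89": 0.415, ">=90": 0.179}
  sex: {male: 0.252, female: 0.748}
  # length-of-stay bands are a model covariate; the source tables print only the
  # overall mean/median, so these shares are a generator choice (median ~24 d)
  los_band: {"<15": 0.32, "15-30": 0.33, ">30": 0.35}
  previous_hospitalization: {"no": 0.75, "yes": 0.25}
  prior_dx: {neither: 0.944, osteo_only: 0.049, osteo_and_fracture: 0.007}
  route:
    home: 0.822
    other_hospital: 0.075
    same_hospital_ward: 0.001
    nursing_welfare_facility: 0.099
    other: 0.003
  admission_type:
    planned: 0.1840
    planned_rehospitalization: 0.0003
    unplanned_nonemergency: 0.3624
    emergency: 0.4533
  cci_band: {"0": 0.55, "1": 0.15, "2": 0.10, "3": 0.07, ">3": 0.13}
  discharge_destination:
    same_hospital_ward: 0.0005
    home_same_hospital_checkup: 0.4145
    home_other_hospital_checkup: 0.0987
    other_hospital_or_facility: 0.3433
    geriatric_facility: 0.0408
    nursing_home: 0.0273
    social_welfare: 0.0466
    died: 0.0171
    other: 0.0112
  meds_at_discharge: {"0": 0.30, "1": 0.35, "2": 0.20, ">=3": 0.15}

# per-category log-odds of treatment receipt at follow-up (natural log of the
# published multivariable odds ratios); omitted categories are reference levels
treatment_log_odds:
  age_band: {"60-69": 0.5822156, "70-79": 0.7467206, "80-89": 0.5877867, ">=90": 0.1310283}
  sex: {female: 0.5709795}
  los_band: {"15-30": 0.2851790, ">30": 0.2623643}
  previous_hospitalization: {"yes": 0.2623643}
  prior_dx: {osteo_only: 0.8878913, osteo_and_fracture: 1.1724958}
  route_group: {other: -0.4155154}
  admission_type_group: {unplanned_nonemergency: 0.3852624, emergency: 0.3646431}
  cci_band: {"1": 0.3220835, "2": 0.4054651, "3": 0.4446858, ">3": 0.5364934}
  destination_group: {hospital: 0.0198026, home: 0.8712934, other_missing: -0.1165338}
  meds_at_discharge: {"1": 1.3297240, "2": 1.6312226, ">=3": 1.8389610}

target_followup_rate: 0.211
index_treatment_rate_by_cohort: {hip: 0.233, vertebrae: 0.405, nvnh: 0.163}
baseline_treatment_rate: 0.083

# first observed regimen mixes per phase (relative frequencies of the
# published "top first observed treatment regimens"; renormalized at load)
regimen_mix:
  baseline:
    bisphosphonate: 0.260
    active_vitamin_D3: 0.231
    active_vitamin_D3+bisphosphonate: 0.141
    teriparatide: 0.061
    vitamin_K2: 0.036
    SERM: 0.026
    active_vitamin_D3+SERM: 0.021
  index:
    active_vitamin_D3: 0.322
    bisphosphonate: 0.164
    active_vitamin_D3+bisphosphonate: 0.129
    teriparatide: 0.101
    vitamin_K2: 0.029
    SERM: 0.021
    active_vitamin_D3+teriparatide: 0.024
    active_vitamin_D3+calcitonin: 0.022
    active_vitamin_D3+calcium: 0.020
  followup:
    bisphosphonate: 0.253
    active_vitamin_D3: 0.245
    active_vitamin_D3+bisphosphonate: 0.181
    teriparatide: 0.125
    vitamin_K2: 0.018
    SERM: 0.015
    active_vitamin_D3+SERM: 0.019
    active_vitamin_D3+teriparatide: 0.016

mpr_histogram:
  "0.00-0.10": 0.363
  ">0.10-0.20": 0.102
  ">0.20-0.30": 0.076
  ">0.30-0.40": 0.047
  ">0.40-0.50": 0.030
  ">0.50-0.60": 0.024
  ">0.60-0.70": 0.021
  ">0.70-0.80": 0.013
  ">0.80-0.90": 0.015
  ">0.90-1.00": 0.308

discontinuation_rate: 0.639
switch_restart_given_disc: 0.436
restart_share: 0.40
augmentation_rate: 0.050
adherent_rate_treated: 0.324

switch_class_mix:
  bisphosphonate: 0.509
  active_vitamin_D3: 0.247
  teriparatide: 0.196
  SERM: 0.017
  calcitonin: 0.016
  vitamin_K2: 0.018
  calcium: 0.018
augment_class_mix:
  active_vitamin_D3: 0.795
  bisphosphonate: 0.455
  calcium: 0.097
  teriparatide: 0.121
  vitamin_K2: 0.043
  SERM: 0.048
  calcitonin: 0.048

supply_days_by_class:
  calcium: 30
  estrogen: 30
  active_vitamin_D3: 30
  bisphosphonate: 30
  SERM: 30
  calcitonin: 30
  teriparatide: 28
  denosumab: 180
  ipriflavone: 30
  nandrolone: 30
  vitamin_K2: 30

# activities-of-daily-living item marginals (overall column of the published
# ADL table); "missing" is the unknown/missing share
adl_marginals:
  eating: {"2": 0.612, "1": 0.294, "0": 0.072, missing: 0.022}
  transferring: {"3": 0.457, "2": 0.326, "1": 0.076, "0": 0.119, missing: 0.022}
  grooming: {"1": 0.517, "0": 0.460, missing: 0.024}
  toilet: {"2": 0.482, "1": 0.268, "0": 0.228, missing: 0.023}
  bathing: {"1": 0.310, "0": 0.649, missing: 0.041}
  walking: {"3": 0.409, "2": 0.190, "1": 0.087, "0": 0.270, missing: 0.045}
  stairs: {"2": 0.316, "1": 0.190, "0": 0.380, missing: 0.115}
  clothing: {"2": 0.392, "1": 0.328, "0": 0.257, missing: 0.023}

# episode-rule knobs
gap_days: 60
regimen_window_days: 14
min_overlap_days: 60
mpr_threshold: 0.80
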