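# Example low-performing peer-group-2 hospital instance ("A").
# Rates are probabilities (peer-group-2 mean as target; hospital's own mean).
# Patient counts are 3-month volumes; costs are triangular (low, fair, high) USD.
# annual_penalty is a placeholder round figure: the source data publishes only
# the percentage penalty (1.35%), not the dollar amount. Replace with your own.
hospital_id: A
annual_penalty: 620000.0
decision_period: 3 months
conditions:
- id: AMI
  target_rate: 0.1597
  hospital_mean_rate: 0.2121
  lambda: 0.25
  n_patients: 52
  cost_triangular: [6745.0, 8431.0, 21078.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: PN
  target_rate: 0.1537
  hospital_mean_rate: 0.1901
  lambda: 0.25
  n_patients: 132
  cost_triangular: [6312.0, 7890.0, 19725.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: HF
  target_rate: 0.2048
  hospital_mean_rate: 0.2243
  lambda: 0.25
  n_patients: 126
  cost_triangular: [5990.0, 7487.0, 18718.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: HK
  target_rate: 0.0801
  hospital_mean_rate: 0.0421
  lambda: 0.25
  n_patients: 96
  cost_triangular: [3585.0, 9359.0, 31814.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: COPD
  target_rate: 0.1867
  hospital_mean_rate: 0.1956
  lambda: 0.25
  n_patients: 47
  cost_triangular: [6460.0, 8075.0, 20188.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: CABG
  target_rate: 0.1515
  hospital_mean_rate: 0.1733
  lambda: 0.25
  n_patients: 21
  cost_triangular: [39864.0, 56297.0, 161385.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
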