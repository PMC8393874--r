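# Example high-performing peer-group-2 hospital instance ("B").
# Same layout as hospital_A.yaml. annual_penalty is a placeholder (source
# publishes only the 0.2% percentage penalty).
hospital_id: B
annual_penalty: 90000.0
decision_period: 3 months
conditions:
- id: AMI
  target_rate: 0.1597
  hospital_mean_rate: 0.1769
  lambda: 0.25
  n_patients: 18
  cost_triangular: [8439.0, 10548.0, 26370.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: PN
  target_rate: 0.1537
  hospital_mean_rate: 0.1469
  lambda: 0.25
  n_patients: 69
  cost_triangular: [7897.0, 9871.0, 24678.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: HF
  target_rate: 0.2048
  hospital_mean_rate: 0.1499
  lambda: 0.25
  n_patients: 44
  cost_triangular: [7494.0, 9367.0, 23418.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: HK
  target_rate: 0.0801
  hospital_mean_rate: 0.0341
  lambda: 0.25
  n_patients: 76
  cost_triangular: [4196.0, 9001.0, 25542.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: COPD
  target_rate: 0.1867
  hospital_mean_rate: 0.1711
  lambda: 0.25
  n_patients: 22
  cost_triangular: [8082.0, 10102.0, 25255.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
- id: CABG
  target_rate: 0.1515
  hospital_mean_rate: 0.1236
  lambda: 0.25
  n_patients: 7
  cost_triangular: [47382.0, 67664.0, 196103.0]
  n_plans: 10
  tier_sizes: [3, 4, 3]
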