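model:
  horizon_cycles: 52
  cycle_length_weeks: 1.0
  wtp: 5180.0
  discount_rate: 0.0
  initial_state: W
  psa_replicates: 1000
transitions:
  W:
    S: 0.097
    A: 0.004
  S:
    W: 0.817
    A: 0.007
  A:
    W: 0.271
    S: 0.052
transition_sds:
  W:
    S: 0.029
    A: 0.002
  S:
    W: 0.038
    A: 0.003
  A:
    W: 0.044
    S: 0.046
utilities:
  W: 0.99
  S: 0.7
  A: 0.31
utility_sds:
  W: 0.016
  S: 0.072
  A: 0.07
costs:
  state_per_cycle:
    W: 13.581376116664318
    S: 44.649138326215898
    A: 914.930033499843603
  state_per_cycle_cv: 0.1
strategies:
- name: EO
  rr_exacerbation: 0.57
  rr_scope: A_entry_only
  rr_sd: 0.2
  test_cost_per_administration: 9.140000000000001
  test_cost_sd: 4.09
  tests_per_year: 16.563066719285299
- name: FeNO
  rr_exacerbation: 0.76
  rr_scope: A_entry_only
  rr_sd: 0.274
  test_cost_per_administration: 2.2
  test_cost_sd: 1.08
  tests_per_year: 16.563066719285299
- name: standard
  rr_exacerbation: 1.0
  rr_scope: A_entry_only
  rr_sd: 0.0
  test_cost_per_administration: 0.0
  test_cost_sd: 0.0
  tests_per_year: 0.0
sa_ranges:
- parameter_id: transition.W.S
  low: 0.07275
  high: 0.12125
- parameter_id: transition.W.A
  low: 0.003
  high: 0.005
- parameter_id: transition.S.W
  low: 0.61275
  high: 0.993
- parameter_id: transition.S.A
  low: 0.00525
  high: 0.00875
- parameter_id: transition.A.W
  low: 0.20325
  high: 0.33875
- parameter_id: transition.A.S
  low: 0.039
  high: 0.065
- parameter_id: utility.W
  low: 0.7425
  high: 1.0
- parameter_id: utility.S
  low: 0.525
  high: 0.875
- parameter_id: utility.A
  low: 0.2325
  high: 0.3875
- parameter_id: state_cost.W
  low: 10.186032087498239
  high: 16.976720145830399
- parameter_id: state_cost.S
  low: 33.486853744661921
  high: 55.811422907769874
- parameter_id: state_cost.A
  low: 686.197525124882759
  high: 1143.662541874804447
- parameter_id: rr.EO
  low: 0.4275
  high: 0.7125
- parameter_id: test_cost.EO
  low: 5.15
  high: 13.199999999999999
- parameter_id: rr.FeNO
  low: 0.57
  high: 0.95
- parameter_id: test_cost.FeNO
  low: 1.2
  high: 4.2
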