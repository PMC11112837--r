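# Baseline cost-model configuration (USD).
# manual: ophthalmologist screening reimbursed at the fundus-photography
# DRG weight; ai: autonomous AI screening at the US 2021 reimbursement.
strategies:
  manual:
    screening_cost: 164
    transport_cost_round_trip: 73
    patient_time_hours: 1.5
    time_cost_per_hour: 24
    visits: 1
  ai:
    screening_cost: 33
    transport_cost_round_trip: 73
    patient_time_hours: 1.0
    time_cost_per_hour: 24
    visits: 1
n_patients: 33
fraction_a: 0.5
nok_per_usd: 9.89
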