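# Example valuation configuration: five record types, a small synergy
# table, default group growth, and marketplace parameters.
types:
  genome:
    base_value: 10.0
    half_life: .inf
    static: true
    display_name: Genome
  cholesterol_panel:
    base_value: 1.0
    half_life: 5.0
    display_name: Cholesterol panel
  blood_test:
    base_value: 1.0
    half_life: 0.5
    display_name: Blood test
  transcriptome:
    base_value: 3.0
    half_life: 1.0
    display_name: Transcriptome
  mri:
    base_value: 5.0
    half_life: 2.0
    display_name: MRI
synergy:
  - types: [blood_test, transcriptome]
    value: 2.0
  - types: [genome, blood_test]
    value: 1.5
  - types: [genome, transcriptome]
    value: 2.5
group_growth:
  form: k_log_k
  C: 1.0
quality_aggregator: reciprocal_sum
max_combination_order: 4
relationship_regularization: true
valuation_time_policy: explicit
marketplace:
  dv_share: 0.1
  validation_timeout: 10
  mint_on_upload: false
  mint_amount: 1.0
  n_keepers: 4
  threshold: 2
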