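jurisdiction: ab_sk
rules:
- rule_id: important_bird_areas
  source: iba
  operator: polygon_burn
  params: {}
- rule_id: ncc_priority_areas
  source: ncc_priority
  operator: polygon_burn
  params: {}
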