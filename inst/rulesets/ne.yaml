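jurisdiction: ne
rules:
- rule_id: wind_wildlife_sensitivity_top4
  source: sensitivity
  operator: category_in_set
  params:
    categories:
    - 3
    - 4
    - 5
    - 6
- rule_id: playa_lakes_high_quality
  source: playa_lakes
  operator: polygon_burn
  params:
    where:
      attr: quality
      values:
      - high
      - very_high
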