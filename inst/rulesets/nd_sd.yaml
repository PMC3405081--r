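jurisdiction: nd_sd
rules:
- rule_id: waterfowl_pair_density
  source: waterfowl_density
  operator: density_at_least
  params:
    threshold: 104.0
- rule_id: tnc_priority_areas
  source: tnc_priority
  operator: polygon_burn
  params: {}
- rule_id: crane_stopover_buffer
  source: crane_obs
  operator: repeated_stopover_buffer
  params:
    radius: 3200.0
- rule_id: river_corridor_buffer
  source: rivers
  operator: line_buffer
  params:
    radius: 1600.0
    where:
      attr: name
      values:
      - Missouri
      - Red
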