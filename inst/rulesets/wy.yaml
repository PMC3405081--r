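jurisdiction: wy
rules:
- rule_id: swap_priority_areas
  source: swap_priority
  operator: polygon_burn
  params: {}
- rule_id: ungulate_migration_corridors
  source: ungulate_corridors
  operator: polygon_burn
  params: {}
- rule_id: ungulate_crucial_ranges
  source: ungulate_ranges
  operator: polygon_burn
  params: {}
- rule_id: sage_grouse_core_rangewide
  source: sage_grouse_core
  operator: polygon_burn
  params: {}
- rule_id: sage_grouse_core_state
  source: wy_core_areas
  operator: polygon_burn
  params: {}
- rule_id: priority_wetland_complexes
  source: wetland_complexes
  operator: polygon_burn
  params: {}
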