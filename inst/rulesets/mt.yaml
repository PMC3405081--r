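jurisdiction: mt
rules:
- rule_id: caps_species_richness_top2
  source: caps_richness
  operator: category_in_set
  params:
    categories:
    - 3
    - 4
- rule_id: caps_conservation_species_top2
  source: caps_species
  operator: category_in_set
  params:
    categories:
    - 3
    - 4
- rule_id: caps_wetlands_top2
  source: caps_wetlands
  operator: category_in_set
  params:
    categories:
    - 3
    - 4
- rule_id: sage_grouse_core_rangewide
  source: sage_grouse_core
  operator: polygon_burn
  params: {}
- rule_id: sage_grouse_core_state
  source: mt_core_areas
  operator: polygon_burn
  params: {}
- rule_id: tnc_priority_areas
  source: tnc_priority
  operator: polygon_burn
  params: {}
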