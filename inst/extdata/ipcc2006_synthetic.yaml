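# Synthetic IPCC-2006-style fallback rates (Mg AGB/ha/yr) for examples and
# tests. These are NOT the published 2006 default values: real applications
# must supply their own config in this schema.
rates:
  - ecozone: tropical_rainforest
    continent: Africa
    secondary_le20: 10.0
    gt20: 3.1
  - ecozone: tropical_rainforest
    continent: NorthSouthAmerica
    secondary_le20: 7.0
    gt20: 1.3
  - ecozone: tropical_rainforest
    continent: Asia
    secondary_le20: 9.0
    gt20: 2.2
  - ecozone: tropical_moist_forest
    continent: Africa
    secondary_le20: 6.0
    gt20: 2.0
  - ecozone: tropical_moist_forest
    continent: NorthSouthAmerica
    secondary_le20: 7.0
    gt20: 1.8
  - ecozone: tropical_moist_forest
    continent: Asia
    secondary_le20: 5.5
    gt20: 1.4
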