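ecozone,continent,agb_at_20,ys_mean
tropical_rainforest,NorthSouthAmerica,118.9,5.9
tropical_mountain_system,NorthSouthAmerica,88.7,4.4
tropical_rainforest,Africa,151.2,7.6
tropical_moist_forest,Africa,57.3,2.9
tropical_rainforest,Asia,68.8,3.4
tropical_moist_forest,Asia,47.1,2.4
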