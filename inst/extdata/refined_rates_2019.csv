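ecozone,continent,forest_type,mean,median,sd,ci_low,ci_high,n
tropical_rainforest,Africa,younger_secondary,7.6,3.5,5.9,4.6,10.6,15
tropical_rainforest,Africa,older_secondary,3.5,1.9,3.3,1.5,5.5,10
tropical_rainforest,Africa,old_growth,1.3,1.7,3.5,0.5,2.1,77
tropical_rainforest,NorthSouthAmerica,younger_secondary,5.9,5.0,2.5,5.1,6.7,42
tropical_rainforest,NorthSouthAmerica,older_secondary,2.3,2.1,1.1,2.0,2.6,39
tropical_rainforest,NorthSouthAmerica,old_growth,1.0,0.9,2.0,0.6,1.4,248
tropical_rainforest,Asia,younger_secondary,3.4,2.1,3.9,0.5,6.3,7
tropical_rainforest,Asia,older_secondary,2.7,2.7,3.1,-1.6,7.0,2
tropical_rainforest,Asia,old_growth,0.7,0.8,2.2,0.1,1.3,66
tropical_moist_forest,Africa,younger_secondary,2.9,2.9,1.0,1.5,4.3,2
tropical_moist_forest,Africa,older_secondary,0.9,0.9,0.7,-0.1,1.9,2
tropical_moist_forest,NorthSouthAmerica,younger_secondary,5.2,4.5,2.3,4.2,6.2,21
tropical_moist_forest,NorthSouthAmerica,older_secondary,2.7,2.2,1.7,1.9,3.5,18
tropical_moist_forest,NorthSouthAmerica,old_growth,0.4,0.8,2.1,-0.7,1.5,19
tropical_moist_forest,Asia,younger_secondary,2.4,2.4,0.3,2.0,2.8,2
tropical_dry_forest,NorthSouthAmerica,younger_secondary,3.9,3.1,2.4,2.0,5.8,6
tropical_dry_forest,NorthSouthAmerica,older_secondary,1.6,1.5,1.1,0.6,2.6,5
tropical_mountain_system,Africa,younger_secondary,5.5,5.5,6.8,-3.9,14.9,2
tropical_mountain_system,NorthSouthAmerica,younger_secondary,4.4,4.0,1.6,3.1,5.7,6
tropical_mountain_system,NorthSouthAmerica,older_secondary,1.8,1.5,0.8,1.0,2.6,4
tropical_mountain_system,NorthSouthAmerica,old_growth,0.5,0.1,1.9,-0.9,1.9,6
tropical_mountain_system,Asia,younger_secondary,2.9,2.9,0.1,2.8,3.0,5
tropical_mountain_system,Asia,older_secondary,1.1,1.2,0.4,0.7,1.5,5
tropical_mountain_system,Asia,old_growth,-0.7,-0.3,3.1,-3.2,1.8,5
subtropical_humid_forest,Asia,younger_secondary,2.5,2.2,0.8,1.7,3.3,4
subtropical_humid_forest,Asia,older_secondary,1.0,0.7,0.9,0.4,1.6,8
subtropical_mountain_system,Asia,younger_secondary,2.5,2.5,0.03,2.5,2.5,2
subtropical_mountain_system,Asia,older_secondary,0.5,0.4,0.3,0.3,0.7,12
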