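table,region,all_mean,all_sd,cv_rms,oa_center,oa_sd,normal_center,normal_sd
min_principal_stress,medial peripheral cortical,-0.36,0.19,5.7,-0.51,0.18,-0.22,0.08
min_principal_stress,medial epiphyseal cortical,-0.59,0.31,6.6,-0.80,0.28,-0.38,0.17
min_principal_stress,medial metaphyseal cortical,-2.06,0.88,7.7,-2.56,0.95,-1.38,0.27
min_principal_stress,medial subchondral cortical,-0.52,0.16,3.9,-0.63,0.18,-0.41,0.06
min_principal_stress,medial subchondral trabecular,-0.46,0.15,3.7,-0.51,0.17,-0.37,0.06
min_principal_stress,medial epiphyseal trabecular,-0.43,0.15,4.8,-0.47,0.18,-0.35,0.06
min_principal_stress,medial metaphyseal trabecular,-0.51,0.26,8.9,-0.55,0.30,-0.34,0.10
min_principal_stress,subchondral spine,-0.30,0.10,5.3,-0.37,0.07,-0.24,0.08
min_principal_stress,epiphyseal central,-0.14,0.06,8.2,-0.16,0.03,-0.14,0.07
min_principal_stress,metaphyseal central,-0.12,0.04,7.3,-0.13,0.03,-0.12,0.05
min_principal_stress,lateral subchondral cortical,-0.32,0.09,5.0,-0.35,0.11,-0.29,0.06
min_principal_stress,lateral subchondral trabecular,-0.25,0.07,4.6,-0.26,0.08,-0.25,0.06
min_principal_stress,lateral epiphyseal trabecular,-0.19,0.05,5.3,-0.20,0.06,-0.19,0.05
min_principal_stress,lateral metaphyseal trabecular,-0.15,0.04,10.5,-0.15,0.04,-0.16,0.06
min_principal_stress,lateral peripheral cortical,-0.22,0.05,5.2,-0.24,0.05,-0.20,0.04
min_principal_stress,lateral epiphyseal cortical,-0.25,0.06,5.9,-0.29,0.06,-0.23,0.04
min_principal_stress,lateral metaphyseal cortical,-0.70,0.21,5.2,-0.76,0.25,-0.65,0.17
min_principal_strain,medial peripheral cortical,1185,512,6.1,1135,561,1236,497
min_principal_strain,medial epiphyseal cortical,1410,601,4.2,1435,666,1385,582
min_principal_strain,medial metaphyseal cortical,1130,418,4.7,1247,433,1014,399
min_principal_strain,medial subchondral cortical,563,203,5.6,536,258,512,143
min_principal_strain,medial subchondral trabecular,770,322,6.5,743,405,627,189
min_principal_strain,medial epiphyseal trabecular,2405,900,3.7,2294,1133,1990,599
min_principal_strain,medial metaphyseal trabecular,2166,933,4.7,2361,1096,1970,771
min_principal_strain,subchondral spine,830,403,7.2,749,544,725,186
min_principal_strain,epiphyseal central,2688,879,3.2,2873,1015,2503,752
min_principal_strain,metaphyseal central,1897,789,4.9,2053,921,1741,668
min_principal_strain,lateral subchondral cortical,862,330,6.4,914,410,809,249
min_principal_strain,lateral subchondral trabecular,1321,447,5.2,1495,548,1148,249
min_principal_strain,lateral epiphyseal trabecular,2508,860,3.9,2434,1006,1979,611
min_principal_strain,lateral metaphyseal trabecular,1940,829,7.5,2080,948,1800,738
min_principal_strain,lateral peripheral cortical,1157,492,5.7,933,657,964,236
min_principal_strain,lateral epiphyseal cortical,1105,403,5.9,1181,475,1030,337
min_principal_strain,lateral metaphyseal cortical,670,288,7.4,656,274,685,323
stiffness,medial compartment,7708,2986,3.6,8515,3767,6902,2190
stiffness,lateral compartment,5959,1545,5.0,6200,1201,5718,1896
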