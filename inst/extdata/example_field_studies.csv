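study_id,site_id,latitude,ecosystem,ph_reported,ph_medium,n_rate,emission_fertilized,emission_control,replicates,map_mm,mat_c,soc,tn,sand_pct,silt_pct,clay_pct
S001,S001-a,35.2,cropland,5.8,H2O,180,2.35,0.82,3,820,12.4,11.2,1.1,38,42,20
S001,S001-b,35.2,cropland,5.9,H2O,240,3.10,0.82,3,820,12.4,11.2,1.1,38,42,20
S002,S002-a,-28.6,grassland,5.2,CaCl2,120,1.04,0.40,4,640,16.8,18.5,1.6,,,
S003,S003-a,51.8,cropland,7.1,H2O,150,1.21,0.55,6,710,9.2,9.8,0.9,25,50,25
S003,S003-b,51.8,cropland,7.0,H2O,300,2.48,0.55,6,710,9.2,9.8,0.9,25,50,25
S004,S004-a,12.4,forest,4.6,KCl,90,0.61,0.30,3,2100,24.1,24.3,2.0,55,28,17
S005,S005-a,40.9,grassland,8.2,,200,1.15,0.62,4,380,7.5,6.1,0.5,62,23,15
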