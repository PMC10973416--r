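sample_id,acetylene,time_h,ppm,soil_dry_mass,bottle_volume,temperature_c,ph_h2o
A0-1,1,2,3.95,0.005,0.1,25,6.1
A0-1,1,4,7.60,0.005,0.1,25,6.1
A0-1,1,6,11.18,0.005,0.1,25,6.1
A0-1,0,2,2.61,0.005,0.1,25,6.1
A0-1,0,4,4.88,0.005,0.1,25,6.1
A0-1,0,6,7.20,0.005,0.1,25,6.1
A2-1,1,2,2.50,0.005,0.1,25,5.3
A2-1,1,4,4.72,0.005,0.1,25,5.3
A2-1,1,6,6.85,0.005,0.1,25,5.3
A2-1,0,2,2.09,0.005,0.1,25,5.3
A2-1,0,4,3.94,0.005,0.1,25,5.3
A2-1,0,6,5.71,0.005,0.1,25,5.3
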