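study_id,sample_id,gene,copies_per_g,ph_h2o,n2o_flux,ecosystem
G001,G001-1,nirK,2.4e7,6.2,58,cropland
G001,G001-1,nirS,1.1e7,6.2,58,cropland
G001,G001-1,nosZ clade I,6.5e6,6.2,58,cropland
G002,G002-1,nirK,8.3e6,5.1,74,grassland
G002,G002-1,nirS,4.0e6,5.1,74,grassland
G002,G002-1,nosZI,1.2e6,5.1,74,grassland
G002,G002-1,nosZ clade II,9.0e5,5.1,74,grassland
G003,G003-1,nirK,1.6e7,7.4,31,forest
G003,G003-1,nirS,9.5e6,7.4,31,forest
G003,G003-1,nosZI,8.8e6,7.4,31,forest
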