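species,diameter_mm_mean,diameter_mm_sd,length_cm_mean,length_cm_sd,density_gcm3_mean,density_gcm3_sd
Pinus sylvestris,0.99,0.07,7.73,0.64,0.510,0.083
Pinus massoniana,0.92,0.09,18.36,2.35,0.483,0.105
Pinus pumila,0.88,0.07,1.48,0.18,0.315,0.032
Picea jezoensis,1.05,0.13,1.82,0.21,0.348,0.021
Larix gmelinii,0.42,0.09,2.22,0.35,0.350,0.045
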