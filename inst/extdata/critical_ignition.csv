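species,peak_ka_mean,peak_ka_sd,action_integral_a2s_mean,action_integral_a2s_sd,energy_j_mean,energy_j_sd,breakdown_kv_mean,breakdown_kv_sd
Pinus sylvestris,101.19,8.80,149418,26272,6650,1169,6.68,0.58
Pinus massoniana,94.76,3.31,132346,9426,6055,431,5.08,0.61
Pinus pumila,102.87,7.29,154918,22500,7160,1040,6.90,0.59
Picea jezoensis,82.64,6.78,100021,16552,4590,760,6.85,0.63
Larix gmelinii,33.67,3.32,16603,3325,803,161,7.52,0.32
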