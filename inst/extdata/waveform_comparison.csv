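waveform,polarity,peak_ka_mean,peak_ka_sd,action_integral_a2s_mean,action_integral_a2s_sd,energy_j_mean,energy_j_sd
8/20,plate_to_electrode,69.83,3.92,74943,8432,3186,358
8/20,electrode_to_plate,67.11,5.79,73440,13087,3454,616
10/350,plate_to_electrode,11.05,0.52,37400,3475,1670,226
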