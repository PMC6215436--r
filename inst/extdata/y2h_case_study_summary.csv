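strategy,potential_dmi,predicted_dmi,mean_random_dmi
Known: ELMi-Protein,62,14,0.122
Known: ELMc-Protein,164,25,0.830
Known: ELMc-Domain,6314,74,9.76
Predicted: ELMc-Protein,39572,204,139
Predicted: ELMc-Domain,969380,1524,1310
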