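primer,tm,n_polymorphic,n_bands,mean_freq,pic
SCoT06,51.70,11,NA,0.64,0.35
SCoT11,58.00,12,NA,0.82,0.25
SCoT12,58.80,7,9,0.69,0.39
SCoT20,64.50,14,15,0.67,0.35
SCoT29,65.70,10,NA,0.72,0.35
SCoT31,63.70,8,NA,0.51,0.37
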