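trait,range,max,min,mean,s,cv,h
M1,29.45,47.50,18.05,32.59,6.81,20.91,2.02
M2,1.40,1.78,0.38,1.06,0.26,24.37,1.79
M3,7.25,13.35,6.10,9.42,1.83,19.40,2.06
M4,2.00,4.00,2.00,2.89,0.56,19.29,1.96
M5,0.96,0.96,0.00,0.10,0.21,221.91,0.86
M6,0.18,0.44,0.26,0.35,0.04,11.69,1.84
M7,0.17,0.50,0.33,0.42,0.08,20.00,0.69
M8,0.62,0.81,0.19,0.43,0.14,33.21,2.03
M9,65.43,104.40,38.97,64.62,16.34,25.29,1.99
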