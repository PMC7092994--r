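session,subject,dpco2_mmHg,dpo2_mmHg,ber_printed
TCD,s4,39.7,42.7,1.1
MRI,s2,36.6,32.7,0.9
MRI,s10,34.3,35.9,1.0
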