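stream,time_h,mean,sd
viability,0,1.00,0.08
viability,1,0.80,0.09
viability,2,0.74,0.07
viability,4,0.60,0.13
viability,6,0.65,0.06
viability,12,0.51,0.07
viability,24,0.52,0.07
viability,48,0.47,0.07
viability,72,0.52,0.07
atp,24,0.18,0.18
atp,48,0.30,0.19
gag,168,0.81,0.04
gag,336,0.87,0.10
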