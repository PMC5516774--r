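stream,time_h,mean,sd
viability,0,1.00,0.08
viability,1,0.73,0.04
viability,2,0.71,0.08
viability,4,0.60,0.02
viability,6,0.43,0.02
viability,12,0.42,0.07
viability,24,0.39,0.04
viability,48,0.39,0.07
viability,72,0.44,0.07
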