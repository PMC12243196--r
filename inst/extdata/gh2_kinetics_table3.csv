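enzyme,mode,kcat_per_min,KM_uM,kcat_over_KM_per_M_s
ZgGH2_7,mm_fit,0.8,67,204
SsGH2_7,mm_fit,4.6,93,824
AmGH2_9,linear,NA,NA,9
BfGH2_9,linear,NA,NA,7
BmGH2_14,mm_fit,2.8,97,488
SdGH2_14,mm_fit,1.2,64,306
CtGH2_23,mm_fit,1.4,40,586
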