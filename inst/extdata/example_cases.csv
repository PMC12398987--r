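case_id,split,f01,f02,f03,f04,f05,f06,f07,f08,f09,f10,f11,f12,f13,f14,f15,f16,p01,p02,p03,p04,p05,p06,p07,p08,p09,p10,p11,p12,p13,p14,p15,p16
1,trainpool,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,.,-,-,-,-,-,-,-,-,-,-,-,-,-,-,-,-
2,trainpool,.,.,.,.,.,.,.,f,.,.,.,.,.,.,.,.,-,-,-,-,-,-,K,B,K,-,-,-,-,-,-,-
3,test,.,.,.,.,.,kw,.,.,.,.,.,.,.,.,.,.,-,-,-,-,-,K,-,-,-,-,-,-,-,-,-,-
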