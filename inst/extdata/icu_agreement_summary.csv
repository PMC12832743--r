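metric,unit,mean_a,sd_a,mean_b,sd_b,bias,loa_low,loa_high,pearson_r
init,mm,4.055,0.583,4.050,0.574,0.005,-0.114,0.123,0.99
end,mm,3.047,0.467,3.024,0.447,0.022,-0.068,0.113,0.996
delta,fraction,0.247,0.051,0.252,0.052,-0.005,-0.021,0.011,0.988
lat,s,0.399,0.030,0.278,0.027,0.121,0.080,0.161,0.742
acv,mm/s,1.274,0.271,1.461,0.297,-0.186,-0.309,-0.063,0.980
adv,mm/s,0.732,0.166,0.776,0.173,-0.044,-0.152,0.064,0.948
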