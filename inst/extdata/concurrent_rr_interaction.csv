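scenario,organ,dose_gy,cycles,rr_published_model,rr,ci_low,ci_high
thyroid_low_medium,thyroid,20,5,4.56,2.3,1.3,4.5
thyroid_high,thyroid,20,10,6.00,2.8,1.1,6.7
breast,breast,25,5,3.20,1.4,0.5,4.2
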