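cycles,rr_published_model,rr,ci_low,ci_high
3,4.1,4.0,1.3,12.5
6,7.0,6.2,2.6,17.1
10,10.6,13.0,4.3,45
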