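cycles,rr_published_model,rr,ci_low,ci_high
3,1.0,0.7,0.3,1.7
6,1.0,0.6,0.3,1.1
10,1.0,0.2,0.1,1.0
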