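cycles,rr_published_model,rr,ci_low,ci_high
5,4.61,1.8,0.3,10.0
10,6.02,9.4,1.4,56.8
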