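organ: breast
lam: 0.4
r: 0.76
'N': 1.0e+06
alpha_R: 0.18
gamma_R: 1.0e-06
alpha_C: 0.2
gamma_C: 1.0e-09
alpha_d: 0.1333
g: 1.2
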