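organ: lung
lam: 0.4
r: 0.96
'N': 1.0e+06
alpha_R: 0.18
gamma_R: 1.0e-06
alpha_C: 0.2
gamma_C: 5.0e-07
alpha_d: 0.1333
g: 0.18
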