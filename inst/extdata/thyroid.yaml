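organ: thyroid
lam: 0.4
r: 0.68
'N': 1.0e+06
alpha_R: 0.25
gamma_R: 1.0e-06
alpha_C: 0.2
gamma_C: 9.0e-08
alpha_d: 0.1333
g: 1.0
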