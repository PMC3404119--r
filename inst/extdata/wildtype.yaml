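# wildtype reference parameters of the reduced clock model
kappa1: 10.0
kappa7: 10.0
kappa6: 90.0
tau1: 1.02
tau7: 1.00
n: 2.0
delta: 1.0
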