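# Default competition-model parameters (uM at the file boundary)
T_total: 0.1
H_total: 10
Ns_total: 0.01
Nu_total: 10
K_s: 0.01
K_h: 0.01
hill_n: 2
unit: uM
fc_thresh: 1
p_thresh: 0.01
flank: 200
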