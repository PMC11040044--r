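Tb: 8.0
To: 30.0
Tm: 42.0
TTemr: 90.0
TTveg: 1000.0
TTrep: 900.0
Pcrit: 12.5
Psens: 100.0
DVIsen: 0.4
mu: 0.015
nu: 2.0
gamma: 14.0
delta: -0.2
k_h: 2.8
lambda_h: 0.4
fc_leaf: 0.4
fc_stem: 0.45
fc_grain: 0.45
initial_carbon: 0.008
reserve_frac: 0.2
remob_rate: 0.05
rue: 1.3
k_ext: 0.6
alpha_leaf: 0.8
beta_leaf: -1.2
alpha_stem: 0.5
beta_stem: -0.6
alpha_harvest: -3.0
beta_harvest: 2.8
alpha_root: 1.0
beta_root: -2.0
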