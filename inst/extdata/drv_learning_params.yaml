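# Learning-set population parameters of the reduced (no-AAG) darunavir
# one-compartment model; the package default (drv_parameters()).
cl_pop: 12.6
v_pop: 137.0
ka_pop: 0.545
theta_sex: -0.198
theta_cyp3a5: -0.192
theta_slco3a1: 0.991
omega_cl: 0.238
omega_v: 0.353
omega_ka: 0.575
sigma_exp: 0.306
sigma_add: 0.611
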