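tau_e: 65.814999999999998
tau_i:             130.13
h_r_e: -78.421999999999997
h_r_i: -72.959000000000003
S_max_e: 0.39534999999999998
S_max_i:            0.15439
mu_e: -51.655999999999999
mu_i: -47.267000000000003
sigma_e: 2.8668999999999998
sigma_i: 4.3250000000000002
h_eq_ee: -5.7891000000000004
h_eq_ei: -1.6566000000000001
h_eq_ie: -86.674999999999997
h_eq_ii: -84.596000000000004
Gamma0_ee: 0.18423999999999999
Gamma0_ei:             1.8771
Gamma0_ie:             1.5969
Gamma0_ii: 1.0838000000000001
delta_ee: 9.1059000000000001
delta_ei: 1.2102999999999999
delta_ie:             2.5985
delta_ii: 9.6945999999999994
N_beta_ee: 3410.8000000000002
N_beta_ei: 2738.9000000000001
N_beta_ie: 863.88999999999999
N_beta_ii: 267.92000000000002
N_alpha_ee: 3616.3000000000002
N_alpha_ei: 2905.0999999999999
lambda_ee:                 24
lambda_ei:                 24
v_ee: 2.1042000000000001
v_ei: 2.1042000000000001
p_ext_ee: 9.3193000000000001
p_ext_ei: 3.1562999999999999
tau_rec_e:                800
tau_rec_i:                600
f_e:               1.25
f_i: 0.17499999999999999
sigmoid_scale: 1.4142135623730951
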