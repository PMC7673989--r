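temperature_c,kd_trans_um,kd_trans_se_um,kd_cis_um,kd_cis_se_um,tau_p_h,tau_p_se_h,tau_pl_h,tau_pl_se_h
10,1.8,0.3,22,2,12.8,0.2,8.3,0.2
21,3.8,0.2,7.0,0.2,2.68,0.02,2.25,0.01
30,7.6,0.7,1.4,0.2,0.99,0.01,0.87,0.01
40,14.2,1.2,0.12,0.01,0.340,0.003,0.327,0.003
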