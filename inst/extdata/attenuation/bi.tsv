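energy_kev	mu_over_rho_cm2_g
30	31.64
40	15.00
50	8.428
60	5.279
80	2.548
90.525	1.983
90.527	7.862
100	5.739
150	2.101
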