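{"gamma":1e-12,"beta_c":1e-11,"k34":0.0005,"k_alpha_deg":0.134,"k_gfp_deg":0.00215,"input_conc":192,"cell_density":5000000,"hill_rep":2,"hill_in":2,"K_u":40,"k_tx":5e-09,"k_tx0":0,"k_tl":0.02,"d_m":0.005,"d_p":0.0001,"d_Z":0.0005,"k_sec":0.001,"k_act":0.01,"k_deact":0.001,"K_L":1e-10,"F_tot":1e-09,"k_gfp":1e-12}
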