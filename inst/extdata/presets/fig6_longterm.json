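{
  "params": {"k_gfp_deg": 0.00215, "input_conc": 192, "k_alpha_deg": 0.134},
  "protocol": "canonical:3h,20h,x3",
  "solver": {"rtol": 1e-10},
  "tasks": ["simulate"]
}
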