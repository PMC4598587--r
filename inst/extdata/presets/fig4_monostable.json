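{
  "params": {"k_alpha_deg": 30, "input_conc": 192},
  "protocol": "canonical:3h,12h,x1",
  "lambda": 0.4,
  "solver": {"rtol": 1e-10},
  "tasks": ["simulate", "score", "stability"],
  "stability": {"n_ic": 4, "horizon_h": 300}
}
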