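{
  "params": {"input_conc": 192},
  "protocol": "canonical:3h,12h,x1",
  "solver": {"rtol": 1e-10},
  "tasks": ["sweep"],
  "sweep": {
    "x": "k_alpha_deg:0.05:50:log:4",
    "lambda_grid": [0, 0.25, 0.5, 0.75, 1]
  }
}
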