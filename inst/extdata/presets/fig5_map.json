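{
  "protocol": "canonical:3h,12h,x1",
  "lambda": 0.4,
  "solver": {"rtol": 1e-10},
  "tasks": ["sweep"],
  "sweep": {
    "x": "k_alpha_deg:0.01:100:log:3",
    "y": "input_conc:40:300:lin:3"
  }
}
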