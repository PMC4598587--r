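{
  "params": {"k_alpha_deg": 0.134, "input_conc": 192},
  "protocol": "canonical:3h,12h,x1",
  "lambda": 0.4,
  "solver": {"rtol": 1e-10},
  "tasks": ["sweep"],
  "sweep": {
    "x": "gamma:1.8e-13:5.6e-12:log:3",
    "y": "k34:1.8e-6:5.6e-4:log:3"
  }
}
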