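{
  "_comment": "Template for transcribing a published rate-constant table. Keys match circuit_params() field names; delete this comment key before use. Units: rates 1/s unless noted; gamma, k_tx, k_tx0, k_gfp in mmol/(ml*s); beta_c, K_L, F_tot in mmol/ml; K_u, input_conc in ug/ml; cell_density in cells/ml.",
  "gamma": null,
  "beta_c": null,
  "k34": null,
  "k_alpha_deg": null,
  "k_gfp_deg": null,
  "input_conc": null,
  "cell_density": null,
  "hill_rep": null,
  "hill_in": null,
  "K_u": null,
  "k_tx": null,
  "k_tx0": null,
  "k_tl": null,
  "d_m": null,
  "d_p": null,
  "d_Z": null,
  "k_sec": null,
  "k_act": null,
  "k_deact": null,
  "K_L": null,
  "F_tot": null,
  "k_gfp": null,
  "overrides": {
    "cell3": {},
    "cell4": {}
  }
}
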