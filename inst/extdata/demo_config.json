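{
  "mode": "grid",
  "truth": {
    ".class": "steady_state_params",
    "G_max": 1.0,
    "K_L": 105.0,
    "K_A": 1.0,
    "n_stoich": 2.33
  },
  "design": {
    "adaptor_levels": [0.1, 0.251188643150958, 0.630957344480193, 1.58489319246111, 3.98107170553497, 10.0],
    "ligand_doses": [1, 3.72759372031494, 13.8949549437314, 51.7947467923121, 193.069772888325, 719.685673001152, 2682.69579527973, 10000],
    "replicates": 3
  },
  "noise": {
    "kind": "multiplicative-lognormal",
    "cv_or_sd": 0.10
  },
  "seed": 1
}
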