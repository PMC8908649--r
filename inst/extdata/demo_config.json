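{
  "seed": 1,
  "run_id": "demo",
  "cohort": {
    "n_group_a": 16,
    "n_group_b": 16,
    "n_regions": 90,
    "n_timepoints": 120,
    "group_b_attenuation": 0.4
  },
  "sparsity": [0.1, 0.2],
  "nulls": {
    "n_random": 20,
    "swaps_per_edge": 10
  }
}
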