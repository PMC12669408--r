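# Sparse grid (at most 3 irregular measurements), no error, alpha = 1.
sim:
  n_pairs: 2000
  alpha: 1
  sigma_e: 0
  grid: {type: sparse, max_k: 3}
methods: [locf, rrc, orc]
n_reps: 1000
base_seed: 1
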