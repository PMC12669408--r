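# Sparse grid, measurement error sigma_e = 0.1, alpha = 3.
sim:
  n_pairs: 2000
  alpha: 3
  sigma_e: 0.1
  grid: {type: sparse, max_k: 3}
methods: [locf, rrc, orc, jm]
n_reps: 1000
base_seed: 1
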