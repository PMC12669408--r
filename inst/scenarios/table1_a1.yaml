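# Dense observation grid (gap 2), no measurement error, alpha = 1.
sim:
  n_pairs: 2000
  alpha: 1
  sigma_e: 0
  grid: {type: dense, gap: 2}
methods: [naive, locf]
n_reps: 1000
base_seed: 1
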