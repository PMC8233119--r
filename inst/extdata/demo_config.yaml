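# Demonstration run: small synthetic twin cohort, all stages.
seed: 42
stages: [simulate, fingerprint, effect_size, heritability]
simulate:
  n_mz_pairs: 30
  n_dz_pairs: 20
  network_sizes: {netA: 8, netB: 8}
  a2_by_network: {netA: 0.4, netB: 0.2}
  c2_by_network: {netA: 0.2, netB: 0.2}
  between: {a2: 0.2, c2: 0.1}
  beta_age: 0.01
  beta_sex: 0.05
  session_noise_sd: 0.5
fingerprint:
  n_perm: 200
heritability:
  subset_size: 10
  n_iterations: 30
  networks: [whole-brain, netA, netB]
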