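# In-silico knock-down ranking against a drugged group generated with a
# known blocked hub protein.
output_dir: out/knockdown_synthetic
seed: 1
epsilon: 0.0005
mode: blocked
rule: additive
synthetic:
  n_obs: 150
  n_proteins: 5
  blocked_node: 2
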