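# Repeated 5-fold cross-validation of the power-law fate model on a
# generated power-law dataset with known ground truth.
output_dir: out/crossval_synthetic
seed: 1
kind: powerlaw
epsilon: 0.0005
synthetic:
  n_obs: 100
  n_proteins: 8
  noise_sd: 0.1
k: 5
repeats: 200
thresholds: [0.7, 0.8, 0.9]
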