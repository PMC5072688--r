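# Within-cell-line 5-fold cross-validation on a converted supplementary
# table (see README for the conversion layout).
output_dir: out/crossval_bt20
seed: 1
kind: powerlaw
epsilon: 1.0e-6
data: inst/extdata/supplementary/lee_BT20.tsv
schema: inst/extdata/supplementary/lee_schema.yaml
fate: apoptosis
k: 5
repeats: 100
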