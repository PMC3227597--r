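# Demonstration pipeline configuration: a small synthetic registry that
# runs end to end in well under a minute.
seed: 20021231
outdir: rbcscreen-demo
synthetic:
  n_mothers: 5000
inclusion_threshold: 0.8
window:
  before_days: 270
  after_days: 14
validation:
  n_pos: 20
  n_neg: 100
  seed: 7
prophylaxis_scope: pregnancy
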