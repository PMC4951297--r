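# Demo configuration: a small synthetic cohort exercising every stage.
seed: 11
outdir: lncsom_demo
simulate:
  enabled: true
  n_groups: 3
  cells_per_group: 15
  n_lnc: 250
  n_modules: 2
  module_size: 15
  stemness_set_size: 12
  subtype_sets:
    sizes: [10, 10, 10, 10]
    effects: [2, 2, 2, 2]
  n_multivariant_genes: 4
structure:
  top_n: 100
  top_k_abundant: 20
som:
  train_n: 80
  epochs: 40
signatures:
  n_random: 50
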