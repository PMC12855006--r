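architecture: varix
latent_dim: 2
beta_final: 0.01
anneal_steepness: 0.75
anneal_midpoint: 0.5
encoding_factor: 4.0
n_hidden: 2
dropout: 0.1
learning_rate: 0.001
weight_decay: 0.0
epochs: 20
batch_size: 8
pretrain_epochs: 0
recon_loss: mse
sim_loss: kl
gamma: 0.0
delta_paired: 0.0
delta_class: 0.0
split:
  train: 0.6
  valid: 0.2
  test: 0.2
seed: 1
filter:
  method: none
  k: ~
scaler:
  method: standard
data:
  rna:
    path: example_rna.tsv
    kind: numeric
  prot:
    path: example_prot.tsv
    kind: numeric
annotation: example_annotation.tsv
tasks:
- column: class
  task: classification
ontology: ~
translate: ~

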