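# Example run configuration for the CLI (`augmem run <config>`).
# The prior is trained from the bundled fixture generator on first use.
task:
  components:
  - type: similarity
    reference: "CCOC(=O)N1CCC(CC1)c1ccc(cc1)OC"
    weight: 1.0
algorithm: augmented_memory
rl:
  sigma: 128.0
  batch_size: 32
  learning_rate: 0.002
  augmentation_rounds: 2
  replay_sample_size: 10
  max_length: 48
budget: 640
seed: 1
buffer_capacity: 100
diversity_filter:
  enabled: false
  bucket_size: 25
selective_purge: false
checkpoint_every: 0
max_epochs: 20
prior_training:
  corpus: fixtures.smi     # e.g. from `augmem make-fixtures fixtures.smi`
  epochs: 70
  lr: 0.005
  emb_size: 48
  hidden_sizes: [128]
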