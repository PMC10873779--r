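# Desk-scale demonstration configuration: 4 synthetic sites x 250
# patients, 40/10/50 split, FedAVG (4 local epochs) for 10 rounds.
cohort:
  n_sites: 4
  n_per_site: 250
  seed: 1
training:
  optimizer: adam
  learning_rate: 0.003
  epochs_per_round: 4
  rounds: 10
  batch_size: 32
k_suppression: 5
output_dir: fedmed-report
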