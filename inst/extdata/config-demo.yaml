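# Example workflow configuration: query-by-committee active learning on the
# Mueller-Brown surface. All quantities are in reduced units.
n_generators: 4          # parallel exploration trajectories
n_committee: 4           # committee size M (trainers and predictors)
n_oracles: 4             # parallel labeling processes
input_dim: 2             # flattened coordinate dimension D
uncertainty_threshold: 1.0   # committee energy spread above which we label
patience: 2              # unreliable steps tolerated before restart
training_buffer_threshold: 16
weight_sync_period: 5    # epochs between weight exports to the predictors
early_stop_patience: 25
max_steps: 1200
enable_oracle: yes
enable_training: yes
reinitialize_on_new_data: no
seed: 1
dt: 0.005
friction: 2.0
temperature: 15.0
mass: 1.0
sampler:
  type: uniform
  lower: [-1.5, -0.2]
  upper: [1.2, 2.0]
hidden_units: 32
learning_rate: 0.02
w_energy: 1.0
w_force: 0.1
epochs_per_flush: 30
val_fraction: 0.1
bootstrap: no
oracle_cost: 4.0         # virtual time per label in the serial scheduler
train_cost: 0.5          # virtual time per training epoch
label_budget: 280
oracle_queue_cap: 8      # pending + in-flight label requests at most this
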