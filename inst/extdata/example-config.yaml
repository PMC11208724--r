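# Training configuration for `cliffopt train`.
# Values marked [method default] follow the published settings of the
# joint objective; the rest are desk-scale choices.
hidden_dim: 32        # embedding width D_h
n_layers: 2           # L, message-passing / refinement layers [method default]
t_steps: 1            # T, molecule-to-atom refinement steps [method default]
lambda1: 0.6          # weight of the adversarial stabilization loss [method default]
lambda2: 0.3          # weight of reconstruction + validity losses [method default]
eta: 5.0              # perturbation norm; match the embedding scale of a single-atom edit
epsilon: 0.01         # probe radius for the adversarial direction
p0: 0.5               # posterior confidence threshold
dropout: 0.1
include_bonds: false  # atom symbols only (the edit the optimizer makes)
task: regression
epochs: 60
batch_size: 32
base_lr: 0.005
warmup_frac: 0.1
seed: 1
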