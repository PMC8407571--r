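# Desk-scale single-hidden-layer image experiment: dendritically normalised
# sparse layer (M = 30, epsilon = 0.2, zeta = 0.15, eta = 0.05,
# minibatch 10) on the synthetic image task. Runs in a few minutes on one
# CPU. Set scheme: "none" for the unnormalised control.
experiment: train
seed: 1
M: 30
layers: 1
epsilon: 0.2
zeta: 0.15
eta: 0.05
minibatch: 10
epochs: 5
n_per_class: 50
n_test_per_class: 20
noise_sd: 0.3
scheme: "0"
excitability: constant
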