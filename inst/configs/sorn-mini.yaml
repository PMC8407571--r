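# Desk-scale self-organising network of spatially extended spiking neurons.
# Set point_neuron: true for the compact-soma control.
experiment: sorn
seed: 1
N_e: 100
N_i: 60
epochs: 25
epoch_len: 300
n_rep: 4
point_neuron: false
n_words_readout: 200
readout_epochs: 10
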