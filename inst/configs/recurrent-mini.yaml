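# Desk-scale recurrent binary-addition experiment with dense feedforward
# and sparse recurrent connectivity under SET. Set sparse_input: true for
# the joint-pool variant, scheme: "none" for the control.
experiment: recurrent-train
seed: 1
M: 50
epsilon: 0.3
zeta: 0.15
eta: 0.05
minibatch: 10
epochs: 20
epoch_len: 250
m_bits: 20
sparse_input: false
scheme: "0"
excitability: constant
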