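# Full-independence limit of the act-then-think model: the private flip in
# the final sub-step drives the stationary dissonance to 1/2.
model: AT
N: 10000
q: 3
p: 1.0
init: ordered
horizon: 500
seed: 1
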