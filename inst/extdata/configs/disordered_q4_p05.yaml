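# High-independence phase at q = 4 (p = 0.5 > p* ~ 0.356): both opinions
# end up equally popular at both levels.
model: TA
N: 10000
q: 4
p: 0.5
init: ordered
horizon: 2000
samples: 10
seed: 1
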