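# Metastable regime (q = 6, p = 0.2): from the ordered state the system
# stays ordered; compare against init: symmetric-random for the hysteresis.
model: AT
N: 10000
q: 6
p: 0.2
init: ordered
horizon: 1000
samples: 10
seed: 1
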