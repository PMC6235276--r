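# Trajectory-variability experiment near the upper spinodal of q = 5:
# individual runs linger in the ordered state before the big turnover, so
# the quantile bands widen with time.
model: TA
N: 10000
q: 5
p: 0.2664
init: ordered
horizon: 2000
samples: 100
seed: 1
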