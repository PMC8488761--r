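# Fixed-benefit model: beneficial mitotype arising in a symbiont-infected host.
schema: 1
model: fixed_benefit
params: {B: 0.075, mu: 0.05, t: 0.02}
mode: trajectory
origin: infected
output: fig1_trajectory.csv
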