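# Cytoplasmic incompatibility: beneficial mitotype arising in an infected host.
schema: 1
model: ci
params: {h: 0.25, mu: 0.05, t: 0.02}
mode: trajectory
origin: infected
output: fig6_trajectory.csv
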