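# Frequency-dependent benefit: beneficial mitotype arising in an uninfected host.
schema: 1
model: freq_dep
params: {b: 0.1, c: 0.05, mu: 0.02, t: 0.02}
mode: trajectory
origin: uninfected
output: fig4_trajectory.csv
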