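# Frequency-dependent benefit: uninfected-origin invasion outcomes over (mu, t).
schema: 1
model: freq_dep
params: {b: 0.1, c: 0.01, mu: 0, t: 0}
mode: sweep
origin: uninfected
grid:
  axis1: {name: mu, from: 0, to: 0.08, "n": 51}
  axis2: {name: t, from: 0, to: 0.05, "n": 51}
output: fig3_sweep.csv
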