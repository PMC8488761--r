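# Fixed-benefit model: uninfected-origin invasion outcomes over (mu, t).
# The symbiont benefit B is a documented default here, not a published value.
schema: 1
model: fixed_benefit
params: {B: 0.1, mu: 0, t: 0}
mode: sweep
origin: uninfected
grid:
  axis1: {name: mu, from: 0, to: 0.1, "n": 51}
  axis2: {name: t, from: 0, to: 0.05, "n": 51}
output: fig2_sweep.csv
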