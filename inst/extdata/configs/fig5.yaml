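# Cytoplasmic incompatibility: uninfected-origin invasion outcomes over (mu, t)
# at one CI strength. The full figure repeats this panel over
# h in {0.01, 0.05, 0.1, 0.25}; change `h` below to regenerate the others.
# Coarse 26x26 grid: each CI cell needs a long bistable run.
schema: 1
model: ci
params: {h: 0.05, mu: 0, t: 0}
mode: sweep
origin: uninfected
grid:
  axis1: {name: mu, from: 0.0002, to: 0.0124, "n": 26}
  axis2: {name: t, from: 0, to: 0.02, "n": 26}
output: fig5_sweep_h0.05.csv
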