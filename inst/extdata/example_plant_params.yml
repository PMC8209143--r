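# Example plant parameter file: the shipped sward defaults, spelled out
# for the parameters users most often change.
gdd: 1400
t_base: 5
sla: 20
t_limit: 5
pmax: 29
wue: 2.5
nc:
  storage: 0.020
  root: 0.012
  leaf: 0.035
  stem: 0.015
resp:
  storage: 0.001
  root: 0.004
  leaf: 0.010
  stem: 0.005
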