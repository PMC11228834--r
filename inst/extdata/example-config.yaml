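# Infinite population, uniform mutant fitnesses, constant decay d = 0.999.
mode: infinite
fitness: uniform
generations: 10000
decay:
  kind: constant
  d: 0.999
replicates: 50
seed: 1
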