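# Example inference configuration for an empirical RADseq dataset:
# exponential root-age prior and a diffuse gamma prior on the shared
# population size.
root_age:
  dist: exponential
  mean: 0.01
alpha_tau: 1.0
pop_size:
  shape: 2.0
  mean: 0.0005
pi: 0.5
mu: 1.0
model: MG
chains: 25
generations: 15000
sample_freq: 10
seed: 1
data: characters.nex
out: run-a
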