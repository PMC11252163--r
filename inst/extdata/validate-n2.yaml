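# Two SPC/Fw molecules in a 20 A box at 300 K: the cross-validation system
# on which the Newtonian and straight event-chain variants and the
# Metropolis reference are compared (waterecmc.R validate --config ...).
system:
  n_molecules: 2
  box_side: 20
  temperature: 300
  seed: 5
engine:
  variant: newtonian
  sampling_interval: 2
  duration: 20000
metropolis:
  n_production: 1000000
  sample_every: 100
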