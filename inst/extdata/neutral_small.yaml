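# Minimal scenario: one neutral population of 150 diploids at
# mutation-selection (here mutation-drift) equilibrium, run 40 generations.
run:
  num_sites: 1.0e6
  num_generations: 40
  compact_interval: 10
  seed: 42
  initial_state: equilibrium
populations:
- size: 150
  mutation_rate: 2.0e-7
sampling:
- {population: 1, sample_size: 12}
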