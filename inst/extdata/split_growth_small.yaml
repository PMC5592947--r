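# Down-scaled split-and-growth scenario: an ancestral population at
# equilibrium under weak purifying selection; at generation 31 a second
# population is founded through a bottleneck of 20 individuals and grows
# exponentially to 200 while exchanging migrants with the source.
run:
  num_sites: 2.0e6
  num_generations: 60
  compact_interval: 10
  seed: 7
  initial_state: equilibrium
populations:
- size: 200
  mutation_rate: 5.0e-8
  selection: -0.001
  dominance: 0.5
- founded: {generation: 31, source: 1}
  mutation_rate: 5.0e-8
  selection: -0.001
  dominance: 0.5
  size:
  - {model: exponential, from_value: 20, to_value: 200, from: 31, to: 60}
migration:
- {from: 1, to: 2, rate: 0.001, start: 31, end: 60}
- {from: 2, to: 1, rate: 0.001, start: 31, end: 60}
sampling:
- {population: 2, sample_size: 10}
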