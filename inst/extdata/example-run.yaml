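# Example run configuration: short adaptive NpT chain on the water-like
# preset with a two-tier surrogate stack (built-in force field generating,
# epsilon-scaled copy assessing through the composite dimer-correction path).
schema_version: 1
system:
  preset: toy_water
  n_molecules: 32
  density: 1.0
simulation:
  ensemble: NpT
  temperature: 300
  pressure: 1
  outer_steps: 200
  period: 20
  dimer_cutoff: 4.0
  adapt: true
  seed: 42
potentials:
  low: {type: ff, r_cut: 4.5}
  medium: {type: ff, r_cut: 4.5}
  high: {type: ff, r_cut: 4.5, epsilon_scale: 1.05}
output:
  directory: out
  series: true
  trajectory: false
  library: true
analysis:
  rdf:
    - pair: [O, O]
      bin_width: 0.05
      r_max: 4.5
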