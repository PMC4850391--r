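# Demo run: 3 subjects, 5 positions, reduced surrogate count.
# Angles are radians in [-pi, pi); times in seconds; SOAs in ms.
experiment:
  entrainment_frequency: 9.6
  n_phase_bins: 8
  layout: exp2
  n_surrogates: 2000
  fdr_q: 0.05
observer:
  threshold: 100
  slope: 8
  guess_rate: 0
  lapse_rate: 0.02
  modulation_depth: [0.52, 0.45, 0.43, 0.40, 0.40]
  local_phase: 0.7853981633974483
  global_phase: -0.7853981633974483
run:
  n_subjects: 3
  targets_per_cell: 33
  seed: 1
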