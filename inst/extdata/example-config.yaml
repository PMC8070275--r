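# Example pleurasound pipeline configuration (desk-scale settings).
# Full-scale equivalents: sample_rate_hz 20000, duration_s 12, n_subjects 4,
# ga population_size 40 / n_generations 30.
generator:
  sample_rate_hz: 8000
  duration_s: 3
  n_subjects: 4
  respiratory_rate_bpm: 15
preprocessing:
  low_hz: 60
  high_hz: 2000
  order: 4
features:
  n_windows: 24
ga:
  population_size: 20
  n_generations: 10
  stopping_patience: 5
tasks: [injury_vs_normal, htx_vs_ptx]
n_permutations: 0
seed: 1
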