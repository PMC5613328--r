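# Frozen toy-world presets: tiny, fully enumerable configurations whose
# one-step expectations are computable in closed form. Loaded by
# make_toy_world(); kept as data so documentation examples and tests never
# drift.
two-otu:
  description: >
    Two OTUs with one-trait phenomes scoring +1 and -1 for both host and
    microbe; two hosts fixed on opposite OTUs. With s = 10 the host
    reproduction probabilities are (100/101, 1/101).
  n_hosts: 2
  capacity: 10
  n_otus: 2
  n_traits: 2
  m: 1
  phenomes: [[1], [2]]
  host_effects: [1, -1]
  microbe_effects: [1, -1]
  init_counts: [[10, 0], [0, 10]]
  ma_percent: 100
  me_percent: 0
  s_h: 10
  s_m: 10
  microbial_mode: tms
  generations: 5
neutral:
  description: >
    Same two-OTU world with both selection coefficients at 1: every fitness
    is 1 and acquisition reduces to multinomial resampling of the source.
  n_hosts: 2
  capacity: 10
  n_otus: 2
  n_traits: 2
  m: 1
  phenomes: [[1], [2]]
  host_effects: [1, -1]
  microbe_effects: [1, -1]
  init_counts: [[5, 5], [5, 5]]
  ma_percent: 50
  me_percent: 50
  s_h: 1
  s_m: 1
  microbial_mode: none
  generations: 5
antagonist:
  description: >
    Microbe-effect scores are the negation of the host-effect scores, so the
    per-host consistency is exactly -1.
  n_hosts: 2
  capacity: 10
  n_otus: 2
  n_traits: 2
  m: 1
  phenomes: [[1], [2]]
  host_effects: [1, -1]
  microbe_effects: [-1, 1]
  init_counts: [[5, 5], [5, 5]]
  ma_percent: 50
  me_percent: 50
  s_h: 10
  s_m: 10
  microbial_mode: tms
  generations: 5
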