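- trait: n_queens
  kind: categorical
  group: tolerance
  transform: none
- trait: colony_size
  kind: quantitative
  group: tolerance
  transform: log
- trait: brood_cycle
  kind: categorical
  group: tolerance
  transform: none
- trait: diet
  kind: fuzzy
  group: niche
  transform: none
  components:
  - seed
  - insect
  - liquid
- trait: diurnality
  kind: categorical
  group: niche
  transform: none
- trait: worker_size
  kind: quantitative
  group: niche
  transform: none
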