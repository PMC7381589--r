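params:
  M_N: 0.0005
  M_H: 0.0005
  human_start: 200.0
  human_end: 2000.0
  introduction_time: 800.0
mutation:
  mu: 2.5e-08
  locus_length: 85
  n_loci: 10000
colonization_time: 20000.0
refugium_ne: 10000.0
generations_per_year: 2.0
chains:
- - 1
  - 2
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
- - 10
  - 11
- - 12
  - 13
  - 14
  - 15
  - 16
demes:
- id: 1
  label: M1
  range: native
  habitat: refugium-mainland
  ne: 2000.0
  founding_time: 0.0
- id: 2
  label: M2
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 19000.0
  source_deme: 1
- id: 3
  label: M3
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 18000.0
  source_deme: 2
- id: 4
  label: M4
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 17000.0
  source_deme: 3
- id: 5
  label: M5
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 16000.0
  source_deme: 4
- id: 6
  label: M6
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 15000.0
  source_deme: 5
- id: 7
  label: M7
  range: native
  habitat: mainland
  ne: 1000.0
  founding_time: 14000.0
  source_deme: 6
- id: 8
  label: M8
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 13000.0
  source_deme: 7
- id: 9
  label: M9
  range: native
  habitat: mainland
  ne: 2000.0
  founding_time: 12000.0
  source_deme: 8
- id: 10
  label: I10
  range: native
  habitat: island
  ne: 2000.0
  founding_time: 19000.0
  source_deme: 1
- id: 11
  label: I11
  range: native
  habitat: island
  ne: 2000.0
  founding_time: 18000.0
  source_deme: 10
- id: 12
  label: X12
  range: introduced
  habitat: introduced
  ne: 2000.0
  founding_time: 800.0
  source_deme: 5
  founder_size: 25.0
- id: 13
  label: X13
  range: introduced
  habitat: introduced
  ne: 2000.0
  founding_time: 800.0
  source_deme: 5
  founder_size: 25.0
- id: 14
  label: X14
  range: introduced
  habitat: introduced
  ne: 2000.0
  founding_time: 800.0
  source_deme: 5
  founder_size: 25.0
- id: 15
  label: X15
  range: introduced
  habitat: introduced
  ne: 1000.0
  founding_time: 800.0
  source_deme: 5
  founder_size: 25.0
- id: 16
  label: X16
  range: introduced
  habitat: introduced
  ne: 200.0
  founding_time: 800.0
  source_deme: 5
  founder_size: 25.0
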