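# Demo pipeline configuration: three populations with a nested split
# history (P1,P2 split 25 generations ago; P3 split from them 60
# generations ago), 20 diploids each.
genome:
  n_chrom: 22
  total_cM: 3500
demography:
  G_max: 300
  m_cM: 1.0
  populations:
    P1: 800
    P2: 800
    P3: 1200
  splits:
    - {a: P1, b: P2, generation: 25}
    - {a: P1, b: P3, generation: 60}
    - {a: P2, b: P3, generation: 60}
  ancestral: 2500
samples_per_pop:
  P1: 20
  P2: 20
  P3: 20
seeds:
  simulate: 11
  cluster: 12
  sharing: 13
  ne: 14
  validate: 15
  surnames: 16
  classify: 17
stages:
  simulate: true
  network: true
  sharing: true
  ne: true
  validate: true
  surnames: true
  classify: true
  pca: false
network:
  min_segment_cM: 4.0
  max_total_cM: 1400
leiden:
  levels: 3
  resolutions: [1.0, 1.0, 1.0]
  min_size: 12
sharing:
  level: level1
  n_boot: 100
ne:
  level: level1
  lambda: 1.0
validate:
  level: level1
  n_perm: 199
  n_boot: 100
surnames:
  level: level1
  origins: [Irish, Scottish, English, Gallowglass]
  enrichment:
    - [0.55, 0.15, 0.2, 0.1]
    - [0.3, 0.4, 0.1, 0.2]
    - [0.25, 0.25, 0.45, 0.05]
classify:
  level: level2
  fraction: 0.8
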