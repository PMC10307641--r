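# Demonstration profile: a small simulated six-stage experiment pushed
# through every pipeline stage. Runs end-to-end in a few minutes on one CPU.
seed: 42
outdir: riboallele_demo
engagement_stages: ["8c"]
classification_stages: ["4c", "8c"]
thresholds:
  engagement_B: 50
  bias_B: 300
  te_B: 200
simulation:
  n_genes: 40
  snp_rate: 3
  frame_fidelity: 0.9
  stop_bias: 10
  start_bias: 4
  duplication_rate: 0.5
  stages:
    - stage: GV
      paternal_fraction: 0
      n_ribo: 2
      n_rna: 2
      reads_per_replicate: 15000
    - stage: MII
      paternal_fraction: 0
      n_ribo: 2
      n_rna: 2
      reads_per_replicate: 15000
    - stage: 1c
      paternal_fraction: 1
      n_ribo: 2
      n_rna: 2
      reads_per_replicate: 15000
    - stage: 2c
      paternal_fraction: 7.1
      n_ribo: 2
      n_rna: 2
      reads_per_replicate: 15000
    - stage: 4c
      paternal_fraction: 30
      n_ribo: 2
      n_rna: 2
      reads_per_replicate: 15000
    - stage: 8c
      paternal_fraction: 47.7
      n_ribo: 3
      n_rna: 3
      reads_per_replicate: 15000
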