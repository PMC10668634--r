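# Default end-to-end pipeline configuration.
# One global seed propagates to per-stage child seeds by fixed offsets.
seed: 7
signatures:
  n_top: 100          # genes per derived cell-type signature
ssgsea:
  weight: 0.75        # rank weight exponent
  min_overlap: 5      # minimum set/matrix gene overlap
association:
  target_group: dualpos
  n_permutations: 1000
nmf:
  k: 3                # factorization rank for sample clustering
  n_restarts: 20
oncogps:
  k_nodes: 9          # map nodes (NMF factors of the module panel)
  n_states: 3
  pull_exponent: 2
  n_restarts: 10
  plant_state: 2      # synthetic state activity added to the target group
  plant_scale: 2
diffexp:
  group_a: dualpos
  group_b: typeII
cells:
  n_cells: 100000
  fractions:          # population fractions for the gating stage
    typeI: 0.324
    typeII: 0.650
    dualpos: 0.026
ct:
  fold_changes:       # ground-truth qPCR fold changes
    Rage: 4
    Aqp5: 2.5
    Sftpc: 1.8
  noise_sd: 0
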