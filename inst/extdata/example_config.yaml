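# Example pipeline configuration for the funneldock CLI.
# Paths are resolved relative to this file's directory.
seed: 1

simulate:
  n_poses: 13        # funnel-shaped decoy ensembles
  n_decoys: 100      # decoys per pose
  n_flat_poses: 0
  n_variants: 1600   # maturation pool records
  n_unique: 89       # unique sequences among them

curate:
  metadata: chains.tsv
  max_resolution: 2.5
  max_mw: 20000

triage:
  poses: poses/            # directory of pose PDBs (chain A)
  competitor: competitor.pdb
  scaffold: scaffold.pdb
  competitor_overlap_min: 30
  scaffold_clash_max: 10
  contact_cutoff: 5.0

landscape:
  decoys: out/decoys.tsv
  min_designs: 50

select-round1:
  decoys: out/decoys.tsv
  k: 20
  min_sasa: 800
  target_count: 16

maturation:
  variants: out/variants.tsv
  k: 100
  reference_flexddg: 0

seqspace:
  variants: out/nonredundant_variants.tsv
  min_cluster_size: 5
  n_score: 20
  n_cluster_picks: 3
  excluded_clusters: []

md-rmsd:
  reference: ref.pdb
  trajectories: [traj1.pdb, traj2.pdb, traj3.pdb, traj4.pdb, traj5.pdb]
  interval: 100
  n_expected: 5
  loops:
    cdr1: [26, 35]
    cdr2: [50, 59]
    cdr3: [97, 111]
    framework: [[1, 25], [36, 49], [60, 96], [112, 126]]
    atom_filter: CA
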