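# funneldock

Decision analytics for computational nanobody dock-and-design campaigns.

Raising a nanobody (VHH) against a chosen epitope *in silico* chains
several engines together — rigid-body docking to generate initial poses,
fixed-backbone interface design to optimize CDR sequences, MM/PBSA and
FlexddG to estimate binding energies, and MD to probe loop stability. The
scientific work between those engines is a series of *decisions*: which
candidate chains to dock, which of tens of thousands of docked poses are
sterically plausible, which poses behave like native binders, which designs
to synthesize, and how to diversify an affinity-maturation pool.
`funneldock` implements those decision stages as tested, deterministic R
code that consumes engine outputs (pose PDBs, score tables, trajectories)
or bundled synthetic stand-ins.

## The methods at its core

* **Chain curation** — candidate nanobody chains are kept when they come
  from X-ray structures at better than 2.5 Å, have all three CDRs
  resolved, are of camelid origin, weigh under 20 kDa, and are
  sequence-non-redundant.
* **Steric triage** — a heavy-atom *clashscore*:
  `1000 · #{(i, j) : d_ij < r_i + r_j − 0.4 Å} / N_pose` over inter-set
  atom pairs with element van der Waals radii. A docked pose is
  *compatible* when it overlaps the competitor it must displace
  (clashscore ≥ 30) while leaving the flanking scaffold domain untouched
  (clashscore < 10).
* **Funnel-landscape selection** — each pose's design decoys form an
  (RMSD, ΔΔG<sub>binding</sub>) scatter. Native-like poses show a funnel:
  energy falls toward the initial pose. Poses pass when they have > 50
  decoys, RMSD and ΔΔG spreads in the top half of the cohort, and the
  energy minimum below the mean RMSD; a closed-form 0–10 `funnel_score()`
  combines depth, slope and slope-gated localization of the landscape.
* **Cycled design selection** — the 20 lowest-ΔΔG designs per pose are
  pooled, interfaces burying < 800 Å² discarded, and 16
  sequence-non-redundant candidates picked by cycling 12 heterogeneous
  ranking/filter criteria sets (diversity by construction).
* **Affinity maturation** — 16 design-protocol variations (4 binary
  parameters), lowest-100 retention per variation (1600 records),
  exact-sequence deduplication, ΔFlexddG referencing, then 20 candidates by
  alternating MM/PBSA and ΔFlexddG rankings plus 3 diversification picks
  nearest the centroids of unrepresented sequence clusters (PCA of
  66 per-residue descriptors → first two components → HDBSCAN-style
  density clustering, implemented in-package).
* **MD loop flexibility** — framework-anchored Kabsch superposition of
  trajectory snapshots, per-CDR Cα RMSD traces, mean/range aggregation
  over independent runs, and one-tailed pooled-variance *t*-tests.

Geometry primitives (Kabsch superposition, Shrake–Rupley SASA, clash
counting, chain mass) are implemented and tested against closed-form and
brute-force oracles. See `vignettes/funneldock-methods.Rmd` for models,
conventions and design choices.

## Worked example

```r
library(funneldock)

# decoy ensembles for 13 candidate poses (stand-ins for design-engine output)
ensembles <- lapply(1:13, function(i)
  gen_decoy_ensemble("funnel", 100, sprintf("pose%02d", i), seed = i))

# funnel-landscape filter over the cohort
verdicts <- funnel_filter(ensembles)$verdicts
head(verdicts[, c("pose_id", "n", "rmsd_std", "ddg_std", "c2", "c3", "c4",
                  "retained")], 3)
#>   pose_id   n rmsd_std  ddg_std    c2    c3   c4 retained
#> 1  pose01 100 1.095191 3.468133  TRUE FALSE TRUE    FALSE
#> 2  pose02 100 1.305661 3.874877  TRUE  TRUE TRUE     TRUE
#> 3  pose03 100 0.910067 3.650475 FALSE  TRUE TRUE    FALSE

# pool the 20 lowest-ddg designs per pose, drop small interfaces, then
# pick 16 non-redundant designs by cycling the 12 criteria sets
pool  <- per_pose_lowest_k(ensembles, 20)   # 260 designs
picks <- cycled_pick(sasa_filter(pool, 800), default_selection_scheme(16))
head(picks[, c("design_id", "pose_id", "ddg", "sasa", "picked_by_set")], 3)
#>      design_id pose_id       ddg      sasa picked_by_set
#> 1 pose09_d0080  pose09 -12.72013  805.9420             1
#> 2 pose08_d0044  pose08 -10.81970 1056.6629             2
#> 3 pose02_d0025  pose02 -11.04380 1005.6352             3

# affinity maturation: dedupe a 1600-record pool to 89 unique variants,
# embed them in sequence space, select 20 by scores + 3 diversification
uniq  <- dedupe_variants(gen_variant_pool(n = 1600, n_unique = 89, seed = 42))
model <- sequence_space_model(uniq)
final <- maturation_select(uniq, model)
table(final$picked_by)
#>     cluster_1     cluster_2     cluster_4 delta_flexddg        mmpbsa
#>             1             1             1            10            10
```

`pose02` is retained because its decoy spreads sit at or above the cohort
medians and its energy minimum lies below the mean RMSD; its
`funnel_score()` of 8.05 (out of 10) marks a strongly funnel-shaped
landscape. The 23 final candidates split into 20 score-driven picks and 3
sequence-space diversification picks.

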