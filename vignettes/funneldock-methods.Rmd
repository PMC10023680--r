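---
title: "Models and numerical conventions in funneldock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical conventions in funneldock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funneldock)
```

`funneldock` covers the decision layer of a nanobody dock-and-design
campaign: everything that happens *between* the engines (docking, design,
energy scoring, MD), operating on their outputs. This vignette records the
models behind each stage, the tunable parameters and their defaults, the
numerical conventions, and what the synthetic generators do and do not
emulate.

## Steric triage and the clashscore dialect

Docked poses are screened with a steric contact metric in the clashscore
family: the number of inter-set atom pairs whose distance falls below the
sum of their van der Waals radii minus an overlap threshold, normalized
per 1000 atoms of the pose being scored.

The canonical crystallographic clashscore is computed after adding
hydrogens; docked-pose inputs here carry none, and adding them would drag
a protonation engine into a screening step. `clash_metrics()` therefore
uses a **heavy-atom-only dialect**: element radii C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80 Å, overlap threshold 0.4 Å, hydrogens ignored. Both the
radius table and the threshold are arguments. The two triage cutoffs —
competitor overlap clashscore ≥ 30 (the pose must displace the native
binder) and scaffold clashscore < 10 (it must not bury into the flanking
domain) — are defaults of `triage_thresholds()`, not constants: because
the dialect differs from the hydrogen-aware original, the numeric
thresholds may not transfer exactly and should be treated as calibration
points for the user's own inputs.

Two optional triage tests mirror docking-time constraints after the fact:
a CDR-contact test (every CDR loop within 5 Å heavy-atom distance of the
antigen; the cutoff is a package choice, exposed as
`contact_cutoff`) and a two-anchor test (Cα of residues 38 and 60, on
CDR1 and CDR2, within 12 Å of the epitope). The anchor test is a
geometric surrogate for a docking restraint that cannot be reproduced
engine-side; its intent — both constrained loops actually face the
epitope — is what is checked.

## Funnel-shaped binding-energy landscapes

Each compatible pose is probed by sampling designs and plotting backbone
RMSD to the initial pose against the interface energy change (ddg). A
native-like pose produces a funnel: energy decreases toward the pose.
`funnel_filter()` retains a pose when

1. more than `min_designs` (50) decoys were generated,
2. its RMSD spread (sample SD, $n-1$ denominator) is at or above the
   cohort median,
3. its ddg spread is at or above the cohort median, and
4. the minimum-ddg decoy lies below the ensemble's mean RMSD
   (ties on ddg resolve to the lowest RMSD).

Medians are computed over the criterion-1 survivors only, because the
filter is sequential and small ensembles carry unreliable spreads.
"Top half" is inclusive (≥ median), so cohorts with many tied spreads do
not empty themselves. Whether spreads use sample or population SD is a
convention; the sample SD was chosen and matters little at $n > 50$.

### The quantitative funnel score

Visual funnel assessment is replaced by a deterministic surrogate on a
0–10 scale:

$$\mathrm{score} = \tfrac{10}{3}\,\big(f_\mathrm{depth}
  + f_\mathrm{slope} + f_\mathrm{slope} \cdot f_\mathrm{loc}\big)$$

* $f_\mathrm{depth} = \mathrm{clamp}_{[0,1]}\!\big(
  (\mathrm{median}(ddg) - \min(ddg)) / \mathrm{range}(ddg)\big)$, defined
  as 0 when the range is 0 (a perfectly flat landscape scores 0 here);
* $f_\mathrm{slope} = \mathrm{clamp}_{[0,1]}(\rho)$ with $\rho$ the
  Spearman correlation of (RMSD, ddg) over decoys with RMSD < 5 Å —
  positive when energy falls toward the pose — and 0 when fewer than 3
  decoys qualify or either variable is constant;
* $f_\mathrm{loc} = 1$ when the minimum-ddg decoy lies within 2 Å of the
  pose, decaying as $e^{-(r-2)}$ beyond. The 2 Å constant reflects the
  steep energy drop expected within ~2 Å of a native pose; it and the
  5 Å slope window are arguments.

The localization term is **gated by the slope term** deliberately. In a
flat landscape the position of the energy minimum is noise, uniform over
the sampled RMSD range, so an ungated localization term would award full
credit to roughly a quarter of featureless landscapes (those whose
accidental minimum lands under 2 Å) and push their scores above the
usual 5-point decision threshold; a visual assessor would never score a
shallow cloud that way, since localization is only evidence of a funnel
when there is a slope for it to localize. With the gate, synthetic funnel
ensembles score ≈ 8 and flat ensembles ≈ 2 (means over 100 generator
seeds), and a threshold of 5 separates the two classes essentially
perfectly.

## First-round design selection

The 20 lowest-ddg designs per selected pose are pooled (ties: lower RMSD,
then design id), designs burying less than 800 Å² of interface are
discarded (the boundary value is kept), and final candidates are picked
in cycled order over a list of criteria sets until the target count (16)
of sequence-non-redundant designs is reached. Each visit picks that set's
top-ranked unpicked design whose sequence is new; redundant designs are
skipped but remain available to later sets.

The shipped `default_selection_scheme()` builds 12 sets as the cross
product of three rankings (ddg ↑, MM/PBSA ↑, funnel score ↓) and four
hard filters (none; buried SASA ≥ 900 Å²; funnel score ≥ 5; MM/PBSA at or
below the pool median). The *mechanism* — diversity through cycling
heterogeneous criteria — is the load-bearing part; the set contents are a
package default and fully user-overridable, since reasonable campaigns
weight energy estimates differently. All tie-breaks are lexicographic
(score, RMSD, design id), making the pick order a pure function of pool
and scheme.

## Affinity maturation and sequence space

`expand_design_grid()` enumerates the $2^4 = 16$ combinations of four
binary protocol parameters (hot-spot forcing, CDR scope, start structure,
design-shell radius), first-declared axis most significant. Per
variation, the 100 lowest-ddg variants are retained (16 × 100 = 1600
records), deduplicated on exact sequence — the representative keeps the
lowest ddg — and referenced to the parent design:
`delta_flexddg = variant − reference`, negative meaning predicted
improvement. The subtraction order is exposed because engines disagree on
sign conventions.

Final selection is two-staged. Stage 1 alternates between the MM/PBSA and
ΔFlexddG rankings, accumulating unique sequences until 20 are picked —
a reconstruction of "best in either or both scores" that guarantees both
scores contribute equally. Stage 2 adds one variant per unrepresented,
non-excluded sequence cluster (up to 3), the member nearest the cluster
centroid, for 23 candidates total. Cluster exclusions are user-specified
because "the clusters already holding the score picks" is a judgment
about a particular pool, not a rule.

### Descriptors, PCA, clustering

Sequences are featurized position-major: each residue maps to a
66-descriptor vector, concatenated over positions. The bundled table
(`inst/extdata/aa_descriptors_synthetic.tsv`) is a **synthetic stand-in**
for published 66-scale descriptor collections: 10 columns are standard
scales (Kyte–Doolittle hydropathy, average residue mass, Zamyatnin
volume, net charge at pH 7, polarity/aromatic/aliphatic/tiny indicators,
side-chain heavy-atom count, H-bonding capability) and 56 are fixed,
standardized synthetic axes that complete the dimensionality. For the
clustering task this matters little — any injective residue embedding
separates sequence differences — but users wanting published scales can
pass any 20 × 66 matrix as `descriptor_table`.

PCA centers columns (no scaling: descriptors share a standardized scale)
and projects onto the top two right singular directions; each component's
sign is fixed so its largest-magnitude loading is positive, making the
projection reproducible. Zero-variance input is an error, not a silent
degenerate projection.

Density clustering is a compact in-package HDBSCAN-family
implementation: mutual-reachability distances from k-NN core distances
(`min_samples` counts the point itself), an exact Prim minimum spanning
tree, a single-linkage hierarchy, a condensed tree at
`min_cluster_size`, and excess-of-mass cluster selection with the root
excluded. Points in no selected cluster are noise (−1). When the
hierarchy never splits into two clusters of `min_cluster_size` (one
compact blob; all points identical) the whole set is one cluster. There
is no randomized initialization anywhere: labels are a pure function of
coordinates and the two size parameters. On two Gaussian blobs
(σ = 0.1, centers 10 apart, 50 + 50 points) it recovers both clusters
with perfect membership, matching an independent reference
implementation.

## MD loop-flexibility analysis

Snapshot schedules exclude $t_0$, so a 10 ns run sampled every 200 ps
yields exactly 50 snapshots and every 100 ps yields 100 — matching how
production-run snapshots are counted downstream; `include_t0 = TRUE` is
available. Each frame is superposed on the reference with a Kabsch fit
over **framework** atoms only, then per-CDR RMSD is computed without
refitting. Anchoring the fit on the framework is essential: fitting on a
loop absorbs the very motion being measured. The "backbone Cα" atom
filter defaults to Cα only; a full-backbone (N, Cα, C, O) mode is one
argument away. Aggregation over independent runs (5 by convention)
reports per-time mean and min/max envelope.

Flexibility comparisons use the pooled-variance (Student) two-sample
*t*-test with a one-tailed p-value in the stated direction; with zero
pooled variance, equal means return $t = 0, p = 0.5$ by convention and
unequal means are an error rather than an infinite statistic. Welch's
correction was not used because run-aggregated RMSD samples come from
identical protocols; the choice is isolated in `compare_flexibility()`.

## Synthetic generators: what they emulate

* `gen_decoy_ensemble()` — funnel landscapes as a Gaussian energy well
  (depth 10, width 1.5 Å, noise SD 1) over half-normal RMSD (σ = 2 Å,
  truncated at 8 Å); flat landscapes as uniform RMSD with independent
  Gaussian energies. These reproduce the *shape classes* of real
  RMSD–ddg scatters, not engine energy scales.
* `gen_clash_complex()` — lattice atom clouds with an exactly planted
  clash count (overlap 0.5 Å per planted pair, all other pairs ≥ 8 Å
  apart), so triage scores have construction-level ground truth.
* `gen_variant_pool()` — maturation pools whose unique variants sit on a
  mutation-load ladder (cluster *k* carries the first 3*k* of a fixed
  motif-substitution list, plus one random extra mutation), with the two
  lowest-load clusters given distinctly better MM/PBSA and ΔFlexddG
  scores (planted correlation 0.6). The ladder makes the between-cluster
  geometry low-dimensional so it survives a two-component projection, and
  the score structure reproduces a pool whose score-driven picks
  concentrate in two clusters while the rest supply diversification —
  the regime the two-stage selection is designed for. Six clusters are
  generated by default so at least three diversification clusters remain
  distinct under any projection.
* `gen_toy_trajectory()` — Cα-only frames with fixed framework,
  scheduled per-loop displacements along fixed random directions,
  optional isotropic loop noise and optional per-frame global rigid
  motion (which superposition must cancel exactly).

All generators take an explicit seed and restore the caller's RNG state;
identical spec + seed gives identical output.

What passing on these fixtures does **not** show: agreement with any
physical energy function, transferability of the 30/10 clashscore
thresholds to hydrogen-aware scoring, behavior of the funnel score on
landscapes that are neither funnel- nor noise-shaped (e.g. multi-minimum
landscapes), or clustering behavior on sequence spaces without planted
structure. Those require real engine outputs.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 13 ensembles × 100
decoys for the first-round arithmetic, 16 × 150 variant records for
retention, 1600-record pools with 89 unique sequences for maturation,
100 + 100 ensembles of 200 decoys for the funnel/flat separation, and
100-point blob sets for clustering — sizes at which every check runs in
seconds on one CPU while the brute-force oracles (O(n²) clash recounts,
full sorts, closed-form SASA) remain exact.

## Known limitations

* PDB input is ATOM/HETATM/MODEL text only — no mmCIF, no altLoc
  handling beyond keeping conformer A, no hydrogen placement.
* SASA uses a deterministic 960-point golden-spiral quadrature; accuracy
  on single spheres is ~0.5% and degrades slightly for deeply buried
  atoms (more quadrature points are an argument away).
* The clustering implementation targets the small 2-D projections this
  pipeline produces (hundreds of points); it is exact but O(n²) in
  memory and time.
* Exact contents of the production selection criteria sets and of the
  score-cluster exclusions are campaign-specific inputs; the shipped
  defaults preserve the mechanisms, not any particular campaign's
  choices.
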