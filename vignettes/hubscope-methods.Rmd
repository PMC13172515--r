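---
title: "Methods: soft contacts, LDS occupancy, interactome calling and flux statistics"
author: "hubscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soft contacts, LDS occupancy, interactome calling and flux statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubscope)
```

`hubscope` is the downstream analysis layer for studies of selective-autophagy
receptor complexes: it quantifies two-chain protein interfaces with a smooth
contact statistic, classifies which partner occupies the LIR-docking site
(LDS) of an ATG8 protein across model ensembles, calls interactors from
label-free quantification (LFQ) matrices, and computes normalized
high-content and FACS flux readouts with their group statistics. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## The soft contact statistic

For two chains $A$ and $B$, the chain-pair contact count is

$$\mathrm{AB}_{\mathrm{cnts}} = \sum_{i \in A} \sum_{j \in B}
  \sigma(|r_{ij}|), \qquad
  \sigma(r) = \tfrac12 - \tfrac12\,\tanh\!\left(\frac{r - a}{b}\right),$$

where the sums run over the selected atoms of the two chains, $a$ is the
cutoff distance and $b$ the smoothing width, both in Å. $\sigma$ is a smooth
step: approximately 1 well below the cutoff, exactly $0.5$ at $r = a$, and
decaying to 0 above it over a width set by $b$. Compared with a hard count
it is differentiable and robust to atoms sitting right at the cutoff.
Residue-pair weights $w_{pq}$ sum $\sigma$ over all selected atom pairs of
residues $p, q$ (a sum, not a max and not binarized, because the statistic
is defined as a double sum over atom positions); `binarize_contact_map()`
offers a thresholded view for plotting only.

Defaults follow the two resolutions the statistic is used at:

| mode | $a$ (Å) | $b$ (Å) | atom selection |
|---|---|---|---|
| `atomistic` | 5 | 0.5 | all heavy atoms (element ≠ H, D) |
| `coarse_grained` | 10 | 1.0 | one designated bead per residue (default name `BB`) |

The bead name is configurable because backbone-bead naming varies between
coarse-grained topologies. Distances are plain Euclidean in Å; there is no
periodic-boundary minimum-image handling — inputs are assumed to be whole,
unwrapped molecules, which is the state of structures after standard
post-processing. `min_distance_map()` reports the minimum selected-atom
distance per residue pair, and `contact_timeseries()` applies the statistic
frame-by-frame over a trajectory.

Numerically, $\sigma$ saturates in double precision once $|r - a|/b$
exceeds about 19 ($\tanh$ rounds to $\pm 1$), so far-apart pairs contribute
exactly 0 and dissolving-interface series become non-increasing rather than
strictly decreasing in their tail. The test suite checks strictness only in
the non-saturating range.

## LIR motifs and LDS occupancy

The LIR core is the 4-residue consensus `[W/F/Y]-x-x-[L/I/V]`. `scan_lir()`
reports every matching window, overlaps included; no upstream acidic-residue
weighting or PSSM scoring is applied — the core consensus is the deliberate
scope, and candidate lists can always be curated by hand.

The LDS of an ATG8 protein is described by two disjoint residue sets lining
its hydrophobic pockets HP1 (which receives the aromatic core position 1)
and HP2 (core position 4). `lds_defaults()` ships curated pocket sets for
GABARAPL2 and LC3B drawn from conserved annotations of the ATG8 family;
they are configuration defaults, not measured quantities, and users mapping
non-standard numbering should supply `lds_definition()` directly.

`classify_binding_mode()` decides which candidate (a LIR motif with ±2
flanking residues, or a whole chain) occupies the LDS of one model:

* per candidate, the soft-contact weight into HP1 and HP2 is summed over
  atom pairs (`pocket_contact_weights()`);
* the occupant is the candidate with the largest HP1+HP2 total, provided
  the total reaches `min_weight` (default 1.0 — roughly one full contact)
  and each pocket individually reaches `min_pocket_weight` (default 0.25,
  so single-pocket grazing does not count as canonical LDS docking);
* if no candidate reaches `min_weight` the model is `unoccupied`; if the
  top two totals differ by less than `margin` (default 10% relative) or the
  top candidate engages only one pocket, the call is `ambiguous`, with the
  provisional occupant chosen by lowest motif start (whole chains rank
  after motifs) so that calls are deterministic under candidate reordering.

These thresholds are explicit configuration (`classification_rules()`) and
are echoed in every `ensemble_occupancy()` result, because published
ensemble-occupancy percentages generally do not state their classification
criterion; percentages computed with other thresholds on other model sets
are not expected to be reproduced by these defaults.
`ensemble_occupancy()` classifies each model independently and reports
counts and percentages per mode, including `unoccupied`/`ambiguous`.

## Interactome calling

`test_enrichment()` computes a per-protein two-sample Student t-test with
pooled variance on log2 intensities (Welch by flag), after
`preprocess_lfq()` has converted zeros to missing, log2-transformed, and
dropped proteins lacking `min_valid_per_group` observations in every
group. The calling rule is the conjunction

$$\text{interactor} \iff q_{\mathrm{FDR}} \le 0.05 \ \wedge\
  \text{enrichment factor} \ge 2,$$

with the one-sided (bait > control) p-value feeding the FDR and the
enrichment factor taken on the linear scale (log2 difference ≥ 1). The
two-sided p-value is carried alongside and is the default volcano y-axis,
matching the common presentation in which calling is one-sided but the
volcano is two-sided; both are configurable. FDR is Benjamini–Hochberg by
default; a Perseus-style permutation FDR (group-label permutation null of
the t statistic, exceedance-ratio q, monotonized) is available because
"5% FDR" in proteomics practice can mean either. Proteins with fewer than
two observations in either group are flagged untestable and excluded from
the FDR family. `impute_missing()` offers the downshifted-normal
convention (per sample, missing values drawn from
$\mathcal N(\bar x - 1.8\,s,\ (0.3\,s)^2)$), seeded; calling can run with
or without it and the mode used is recorded in the result metadata.

`pairwise_fc_gate()` (linear-scale condition-mean ratio ≥ threshold,
boundary inclusive) and `condition_zscore()` (per-protein z-score of
condition-average intensities; zero-variance rows flagged and set to 0)
support the standard two-condition scatter and heatmap summaries.

## Flux statistics

Per-cell readouts are ratios (`ratio_metric()`: e.g. marker-in-lysosome
over marker-total, or surface over total), with non-positive denominators
excluded and counted. `normalize_to_reference()` divides by the untreated
reference mean *within each stratum* (experiment or biological replicate),
so the reference mean is exactly 1 in every stratum; normalization is
idempotent. Both per-well-then-normalize (`well_aggregate()`) and per-cell
paths are supported and must be selected explicitly, since published
panels differ in which they use.

Group statistics follow the conventions of high-content flux figures:
two-sided one-sample t against 1 for normalized grouped conditions
(`one_sample_test()`; sd = 0 is flagged untestable), two-sided Wilcoxon
rank-sum tests with BH correction across the comparison family
(`group_compare()`), Tukey box summaries (`box_summary()`: type-7
interpolated quartiles, whiskers at the most extreme points within
1.5×IQR), and star annotations (`p_stars()`). The Wilcoxon p is exact when
there are no ties and combined $n \le 25$, otherwise the normal
approximation with mid-ranks, tie-corrected variance and continuity
correction is used; the switch is deliberate and documented because exact
enumeration is both exact and cheap at these sizes, while large per-cell
samples make the approximation indistinguishable. FACS tandem-reporter
fold changes (`mfi_fold_change()`) use the mCherry/GFP MFI ratio by
default (the ratio rises as GFP quenches in acidic lysosomes; the
orientation is configurable) normalized to each cell line's untreated
mean.

## Synthetic data and what passing tests show

Each generator is a pure function of configuration and seed and returns a
truth record alongside the data:

* `gen_two_chain_complex()` — single-heavy-atom residues, 30 Å chain
  spacing, planted pairs at exact requested distances, everything else
  > 30 Å apart (beyond 3× either default cutoff). One atom per residue
  keeps the brute-force oracle trivial and isolates the $\sigma$ math from
  geometry bookkeeping.
* `gen_mode_ensemble()` — a toy ATG8-like chain with two 4-atom pockets
  8 Å apart and one candidate chain per mode; the planted candidate's core
  spans both pockets (total pocket weight ≈ 14, more than 10× the default
  `min_weight`), all others are parked > 150 Å away. Mode counts use
  largest-remainder rounding so fraction recovery is exact (e.g. 25 models
  at 72%/28% give exactly 18 and 7).
* `gen_decay_trajectory()` — rigid +y translation of one chain by
  $k\,\Delta$ in frame $k$; every inter-chain distance grows monotonically,
  so any contact series over it must be non-increasing.
* `gen_lfq()` — baseline log2 abundances $\mathcal N(25, 2^2)$ (typical of
  LFQ intensity scales), replicate noise $\mathcal N(0, 0.3^2)$ by default,
  spike shifts added in the bait group, completely-at-random missingness.
  Intensity-dependent missingness is deliberately excluded: it would
  change the imputation-calibration claims, and the null models here are
  stated as MCAR.
* `gen_cell_table()` / `gen_facs_table()` — per-group normal features
  clamped at 0 and round-robin well assignment; FACS ratios with planted
  multiplicative effects and relative noise.

The generators emulate *effect structure and noise*, not realism: no AF2
confidence correlation between models, no spectral or segmentation noise,
no batch effects, no intensity-dependent dropout. Passing recovery tests
therefore demonstrates that the statistics and classifiers implement their
contracts and recover known truth under their stated assumptions — not
that those assumptions hold in any particular real dataset.

## Problem sizes and validation choices

The test suite validates the contact and distance maps against plain
nested-loop oracles on 100 randomized complexes of up to 50 atoms, BH
against the step-up formula on 1000 random p-vectors, and the exact
Wilcoxon p against full enumeration for all group sizes with combined
$n \le 12$. Interactor-calling calibration uses 200 null LFQ replicates
(2000 proteins, 3 vs 3) and spike recovery 100 replicates with 20 spiked
proteins (log2 effect 3, within-group sd 0.3) — a 1% interactor fraction,
a realistic order for an affinity-purification experiment. Planted-effect
recovery for the cell-table path uses 100 replicates of 500 cells per
group with a +50% surface/total shift.

## Known limitations

* With $n = 3$ per group the pooled t has 4 degrees of freedom; its heavy
  tail means a small spiked family (tens of proteins among thousands)
  loses roughly 10% of spikes to the BH cutoff even at log2 effect 3 and
  sd 0.3. The per-spike recovery probability rises with the spiked
  fraction (the BH cutoff scales with family size); near-complete
  (≥ 99%) recovery at these noise settings requires the enriched set to be
  roughly ≥ 5% of the tested family. The corresponding recovery test in
  this package documents this by failing at the 1% fraction — the honest
  power of the rule at those sizes — and the same number is obtained
  through an independent `t.test`/`p.adjust` route.
* The PDB reader covers ATOM/HETATM/MODEL/ENDMDL with fixed columns,
  altloc resolution (highest occupancy, tie → first) and insertion codes;
  it does not read mmCIF, and the trajectory reader covers multi-model PDB
  and XYZ blocks only — binary trajectory formats are out of scope.
* The LDS defaults are curation; classification on real ensembles should
  report, and if needed sweep, the thresholds (`classification_rules()`),
  which every occupancy summary echoes.
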