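# hubscope

Analysis toolkit for studies of selective-autophagy receptor complexes —
the computational layer that sits downstream of structure prediction,
molecular simulation, mass spectrometry and high-content imaging. It is
aimed at structural and cell biologists who need reproducible, tested
implementations of four recurring analyses:

1. **Soft-contact interface analysis.** The chain-pair contact count
   between chains A and B,

   AB_cnts = Σ_{i∈A} Σ_{j∈B} σ(|r_ij|),  σ(r) = ½ − ½·tanh((r − a)/b),

   a smooth sigmoidal counting function that limits contributions to atom
   pairs below the cutoff *a* (σ(a) = 0.5), with smoothing width *b*.
   Defaults: a = 5 Å, b = 0.5 over heavy atoms (atomistic); a = 10 Å,
   b = 1.0 over one backbone bead per residue (coarse-grained). Residue
   contact maps, minimum-distance maps and per-frame trajectory series.

2. **LIR–LDS binding-mode classification.** Scans sequences for the
   4-residue LIR core `[W/F/Y]-x-x-[L/I/V]`, measures each candidate's
   soft-contact weight into the two hydrophobic pockets (HP1/HP2) of an
   ATG8 protein's LIR-docking site, classifies the occupant per model
   under explicit thresholds, and aggregates occupancy percentages over
   model ensembles.

3. **Label-free interactome calling.** Per-protein one-sided two-sample
   Student t-tests (pooled variance) on log2 LFQ intensities; a protein is
   an interactor when it passes 5% FDR (Benjamini–Hochberg, or a
   permutation alternative) with a minimal enrichment factor of two.
   Volcano coordinates, pairwise fold-change gates and condition z-score
   heatmap values included.

4. **Autophagy-flux statistics.** Per-cell ratio metrics, normalization to
   the untreated reference mean within each experiment/replicate stratum
   (reference mean ≡ 1), per-well aggregation, one-sample t-tests against
   1, Wilcoxon rank-sum comparisons with BH correction, Tukey box
   summaries, and tandem-reporter (mCherry/GFP) FACS fold changes.

Every stage has a seeded synthetic-data generator with recorded ground
truth (`gen_*` functions), so all recovery claims are testable end-to-end.

## Worked example

Build a 25-model ensemble in which 18 models dock the LIR1 core into both
LDS pockets and 7 dock an alternative partner, then classify every model
from geometry alone:

```r
library(hubscope)

e   <- gen_mode_ensemble(25, c("LIR1-LDS" = 0.72, "ATG7-LDS" = 0.28), seed = 11)
occ <- ensemble_occupancy(e$ensemble, e$lds, e$candidates)
occ
#> occupancy_summary over 25 models:
#>  mode_label count percent
#>    LIR1-LDS    18      72
#>    ATG7-LDS     7      28
```

The percentages are produced by the geometric classifier (default rules:
total pocket weight ≥ 1, each pocket ≥ 0.25, 10% relative margin), not by
the planted labels — 72% of models carry the LIR1-in-LDS binding mode.

Call interactors on a spiked LFQ matrix (2000 proteins, 3 vs 3, 20 spiked
at log2 effect 3):

```r
g      <- gen_lfq(2000, 20, log2_effect = 3, within_sd = 0.3, seed = 11)
called <- call_interactors(test_enrichment(preprocess_lfq(g$lfq), "bait", "control"))
sum(called$interactor)
#> [1] 18
head(called[called$interactor, c("protein_id", "difference", "q_fdr", "enrichment_factor")], 3)
#>        protein_id difference      q_fdr enrichment_factor
#> P00034     P00034   2.936123 0.01323481          7.653517
#> P00062     P00062   3.130035 0.02107809          8.754560
#> P00093     P00093   3.177313 0.01382953          9.046209
```

All 18 calls are true spikes (the `difference` column is the t-test
difference in log2 units; `enrichment_factor` = 2^difference); the two
missed spikes reflect the power of a df = 4 t-test under BH at this spike
fraction, discussed in the methods vignette.

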