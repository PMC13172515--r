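Package: hubscope
Title: Soft-Contact Interface Analysis, LIR-LDS Binding-Mode Classification,
    Interactome Calling and Autophagy Flux Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis layer for studies of selective-autophagy receptor
    complexes. Implements a smooth sigmoidal residue-residue contact
    statistic for two-chain protein interfaces over single structures,
    model ensembles and trajectories; scans sequences for the four-residue
    LIR core motif and classifies which binding partner occupies the
    LIR-docking site (LDS) of an ATG8 protein, with ensemble occupancy
    summaries; calls interactors from label-free quantification (LFQ)
    intensity matrices with a one-sided two-sample t-test, FDR control and
    a minimum enrichment factor; and computes normalized high-content and
    FACS autophagy-flux readouts with their group statistics. Every stage
    is backed by seeded synthetic-data generators with recorded ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    bio3d,
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
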