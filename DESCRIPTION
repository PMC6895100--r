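Package: tRNAcp
Title: Discovery and Characterization Workflow for acp3U tRNA Modifications
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational workflow used to discover and
    characterize 3-(3-amino-3-carboxypropyl)uridine (acp3U) in transfer RNA:
    a modification-aware RNA sequence representation with Sprinzl position
    numbering, phylogenetic profiling of ortholog presence/absence against a
    modification phenotype, in-silico RNase digestion with exact monoisotopic
    mass and CID product-ion computation for oligonucleotide LC/MS, detection
    of acp3U sites from reverse-transcription misincorporation signatures in
    tRNA-seq pileups, two-state UV melting-curve simulation and
    inflection-point Tm estimation, and the small descriptive statistics of
    the associated phenotype assays. Seeded synthetic-data generators make
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    igraph,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, Epitranscriptomics, MassSpectrometry, Sequencing
RoxygenNote: 7.3.3
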