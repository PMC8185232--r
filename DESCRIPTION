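Package: kegomics
Title: Multi-Omics Harmonization via iTRAQ Rollup, Abundance-Localized
    Z-Scores and KEGG-Ortholog Integration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonizes isobaric-label (iTRAQ 8-plex) proteomics,
    RNA-Seq transcript counts and internal-standard-normalized
    metabolite abundances onto a common z-score scale for knock-out
    versus wild-type study designs. Implements spectrum-to-protein
    rollup with reference-pool alignment across plexes, ranked
    sliding-window MA-plot z-scores that standardize log2 fold
    changes by local abundance, collapsing of transcripts and
    proteins into KEGG Orthology (KEGO) enzyme families,
    transcript-metabolite-protein reaction-triad clustering, and
    construction of phenotype-correlated protein interaction
    networks with SIF export. A seeded synthetic-study generator
    with known ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Transcriptomics, Metabolomics, Network,
    Normalization, MassSpectrometry
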