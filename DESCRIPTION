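Package: epistitch
Title: Epitope-Prioritized Peptide Library Design and PhIP-Seq Reactivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing compact phage-display (PhIP-Seq) peptide
    libraries and analysing the resulting antibody reactivity data. A
    composition-based random-forest classifier prioritizes 15-mer windows of
    proteins by their probability of containing a linear B-cell epitope; a
    stitching step packs three predicted epitopes per synthesized 56-residue
    peptide; an oligo encoder produces synthesis-ready 200-nt sequences via
    codon-usage-weighted reverse translation with restriction-site recoding;
    and a permutation z-score (phage aggregate reactivity score) summarizes
    antibody reactivity per phage from peptide-level fold changes. A
    synthetic-data module generates proteomes with planted epitopes, scan
    library reactivity and PhIP-Seq count matrices for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
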