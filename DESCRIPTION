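Package: nucsig
Title: Nucleosome-Centered Mutation Signature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dissecting how nucleosome structure shapes
    UV mutagenesis. Calls nucleosome dyads from per-base positioning-score
    tracks with a greedy exclusion algorithm, builds 147-bp dyad-centered
    profiles of somatic mutations and UV lesion/repair reads, normalizes
    observed mutations by a trinucleotide-context expected model, quantifies
    rotational (~10 bp) periodicity with a Lomb-Scargle periodogram and
    translational curvature with quadratic fits, and stratifies nucleosomes by
    chromatin state, histone-peak membership, and transcription level. A
    synthetic-data module generates genomes, dyads, mutations, and assay reads
    with injected periodic and quadratic signal so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
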