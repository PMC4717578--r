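Package: trimscape
Title: Discovery and Characterization of Terminal-Repeat Retrotransposons in
    Miniature (TRIMs)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A structural-annotation pipeline for terminal-repeat
    retrotransposons in miniature (TRIMs), small non-autonomous LTR
    retroelements of plant genomes. Provides de novo detection of miniature
    LTR-element candidates (paired direct repeats with target-site
    duplications), TRIM-defining filters, subfamily and family clustering
    under the 80/80 rule, library-based genome masking and copy-number
    summaries, tandem-array structure classification, genic-context and
    gene-capture analyses with a Nei-Gojobori Ka/Ks estimator, bisulfite
    methylation and small-RNA profiling of elements, and comparative analyses
    that locate autonomous partner elements, internal-deletion breakpoints,
    and insertion polymorphisms between assemblies. Includes a synthetic-data
    generator that implants TRIMs, solo LTRs, tandem arrays, genes,
    methylomes, and small-RNA alignments with full ground truth, so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    igraph,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
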