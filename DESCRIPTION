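Package: satmine
Title: De Novo Discovery and Comparative Analysis of Candidate Centromere
    Tandem Repeats from Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies candidate centromere tandem repeat monomers de novo
    from unassembled shotgun reads of any sequencing technology.  Long reads
    (Sanger, PacBio) are scanned directly with a wraparound dynamic-programming
    tandem repeat detector; short reads are routed through a k-mer de Bruijn
    cycle reconstructor that recovers monomers longer than the read length.
    Per-read hits are canonicalized (rotation- and strand-invariant),
    clustered into repeat families, and ranked by abundance to nominate the
    candidate centromere repeat.  Downstream analyses cover higher-order
    repeat (HOR) detection with monomer-instance clustering, circular-
    permutation-tolerant global identity between species' monomers,
    node-averaged identity decay with divergence time (H ~ alpha * t^lambda),
    and phylogenetic signal of repeat traits (Blomberg's K).  A synthetic-data
    module generates genomes with planted polymorphic tandem arrays, reads of
    three technology regimes, Brownian-motion traits and diverging monomer
    families for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn,
    igraph,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
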