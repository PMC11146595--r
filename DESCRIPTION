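Package: rdgraph
Title: Ribosome Decision Graphs for Modeling mRNA Translation Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ribosome decision graphs (RDGs), a rooted directed acyclic
    graph abstraction of eukaryotic mRNA translation in which nondeterministic
    ribosome events (leaky-scanning initiation, reinitiation after short
    translons, stop-codon readthrough, selenocysteine insertion and programmed
    ribosomal frameshifting) are branch points and translated regions
    ("translons") label elongation edges. Provides ORF and start-site scanning
    on transcript sequences, enumeration and exact counting of ribosome paths,
    inference of branch probabilities from ribosome-profiling A-site footprint
    density, stochastic simulation of footprint data, application of transcript
    variants with topology diffing, and readers/writers for FASTA, bedGraph,
    wiggle, BED-like event files, JSON graph documents and DOT renderings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
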