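Package: TEscout
Title: De Novo Detection of Transposable Element Mobilization from
    Discordant Read-Pair Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transposition events, both the new insertion site
    (acceptor) and the mobilized source element (donor), from discordant
    read-pair signatures in whole-genome resequencing alignments, without
    requiring prior transposon annotation. Read-pair mappings are classified
    by orientation, chromosome and insert size into deletion, insertion,
    duplication, inversion and translocation signatures; same-signature
    pairs are clustered by seeded single-linkage in mate-position space over
    a grid of linking thresholds, and clusters are assembled into insertion
    calls through a donor-side overlap condition. The package also
    attributes each insertion to its true donor among near-identical element
    copies by counting reads that map strictly better to one candidate,
    masks ambiguous acceptor regions using GC-corrected read depth, and
    ships a mate-pair read simulator (empirical quality profiles,
    circularization chimeras, short-fragment contamination) together with a
    transposition-event injector and an evaluation protocol for end-to-end
    benchmarking on synthetic genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
biocViews: StructuralVariation, Transposon, Sequencing, Alignment,
    Coverage, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
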