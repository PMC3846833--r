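Package: crypticsplice
Title: Cryptic-Intron Discovery and Characterization of a Myostatin Splice Variant
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for discovering and characterizing cryptic
    introns inside annotated exons, built around the sheep myostatin splice
    variant (MSV). Provides splice-signal scanning (GT donor, AG acceptor,
    YNYTRAY branch point, polypyrimidine tract), in-silico splicing with ORF
    reconstruction and the 50-nt nonsense-mediated-decay rule, proprotein
    convertase and furin cleavage-site prediction with molecular-weight
    calculation, restriction-fragment prediction with probe hybridization
    (in-silico Southern), rule-based cross-species conservation classification,
    1:1 Langmuir surface plasmon resonance sensorgram simulation and global
    kinetic fitting, and a ground-truthed synthetic-data generator so every
    stage is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
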