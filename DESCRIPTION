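Package: pprhtools
Title: Design and In-Silico Validation of Editing Polypurine Reverse-Hoogsteen Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing editing polypurine reverse-Hoogsteen
    hairpins (PPRHs): single-stranded DNA hairpins of two mirror-repeat
    polypurine arms joined by a pentathymidine loop, extended at the 5' end
    through a pentathymidine linker with a homology tail spanning an edit
    junction. Finds polypurine tracks (polypyrimidine targets) in a reference
    sequence, assembles and decomposes editing PPRHs, and verifies designs
    with sequence-level assays: restriction-site scans, virtual PCR, splice
    isoform enumeration with RT-PCR band-size prediction, and oligonucleotide
    physicochemistry (molecular weight, GC content, melting temperature, dose
    to molarity conversion). Ships a seeded synthetic minigene generator
    emulating an exon-duplication construct and its edited reversion so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
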