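Package: famec
Title: Lossless Reference-Based Compression of FASTA Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lossless codec for multi-FASTA genome collections built on
    relative compression against a dynamically growing reference buffer.
    Contigs are parsed into direct and reverse-complement maximal exact
    matches; the unmatched remainder is coded with an exclusive mismatch
    encoding matrix, per-base coding in gaps between corresponding matches,
    score-bounded adjacent encoding around matches, a gap-breaks filter for
    short interrupting matches, and gaps-delta coding of match offsets. The
    logical streams are entropy-compressed with an LZMA-class backend into a
    single archive supporting listing, selective extraction, appending and
    repacking. Includes a seeded synthetic genome-collection generator (SNPs,
    indels, inversions, translocations, N runs, soft-masking) and a command
    line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'famec-package.R'
    'streams.R'
    'AllClasses.R'
    'fasta-io.R'
    'synthetic.R'
    'mem-index.R'
    'match-model.R'
    'approx-codec.R'
    'archive.R'
    'cli.R'
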