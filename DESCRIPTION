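Package: RNAtangles
Title: Prime Tangle Factorization of RNA Secondary Structures in the Brauer Monoid
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models RNA secondary structures, including pseudoknots, as tangles
    of the Brauer monoid and computes minimal prime factorizations. Extended
    dot-bracket strings or BPSEQ files are flattened to arc diagrams, reduced to
    abstract shapes by discarding unpaired nucleotides and collapsing stacked
    arcs, and folded into tangles. Tangles are classified (all-transversal,
    Temperley-Lieb, small-hook, big-hook) and factorized into T- and U-prime
    generator words by class-specific algorithms: adjacent-transposition
    sorting, a region-based Temperley-Lieb reader, and two hook-merging
    heuristics. A native term-rewriting engine over the thirteen prime-tangle
    identities minimizes factor words, and a breadth-first Cayley-graph oracle
    certifies minimality at small N. Includes seeded generators for random
    tangles and random (pseudoknotted) secondary structures, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'tangle-core.R'
    'factor-word.R'
    'rna-shape.R'
    'factorize.R'
    'rewrite.R'
    'oracle.R'
    'synthetic.R'
    'pipeline.R'
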