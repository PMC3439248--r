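Package: annomatch
Title: Pairwise Comparison of Gene Structure Annotation Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compares two gene structure annotation sets (GFF3) covering the
    same genomic sequences. Gene loci are identified as connected components
    of the joint gene-overlap interval graph; at each locus, transcripts from
    each source are collapsed into maximal cliques of mutually non-overlapping
    transcripts (Bron-Kerbosch enumeration) and encoded as per-position model
    vectors over the alphabet {C, F, G, I, T} (coding, 5'-UTR, intergenic,
    intron, 3'-UTR). Similarity is scored at nucleotide and feature
    resolution (sensitivity, specificity, F1, annotation edit distance,
    simple matching coefficient, correlation coefficient, overall identity),
    each comparison is classified by structural congruence, and results are
    rendered as per-locus text reports, an aggregate summary, and an optional
    GFF3 locus track. A synthetic paired-annotation generator with known
    ground truth supports controlled evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
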