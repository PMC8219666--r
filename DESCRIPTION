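Package: retrofind
Title: Detection, Genotyping and Structural Annotation of Nonreference
    Transposable Element Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies nonreference transposable element (TE) insertions
    from coordinate-sorted short-read and long-read whole-genome alignments.
    Short-read discovery starts from soft-clipped reads and validates
    candidates by the consistency of clip and discordant-mate clusters on
    the TE consensus; long-read discovery groups clipped reads and CIGAR
    insertion operations, locally assembles supporting reads and extracts
    the full insertion sequence between realigned reference flanks.
    Additional modules call genotypes with a random-forest classifier over
    a fixed 14-feature schema, detect somatic insertions against a matched
    control with clonality-aware thresholds, and annotate L1 internal
    structure, processed pseudogenes, centromeric ghost L1s, dimorphic
    HERVs and TE-insertion-mediated structural variants. A deterministic
    simulator generates miniature references, planted insertion events and
    analytically aligned reads with ground-truth records for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
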