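Package: wgaprofiler
Title: Profiling Chimera, Coverage and GC Biases in Whole-Genome Amplified Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and quantify the artifacts that whole-genome
    amplification (WGA, in particular multiple displacement amplification with
    Phi29 polymerase) introduces into Illumina short- and long-insert
    sequencing libraries. Provides a truth-tracked simulator of amplified
    fragment populations carrying priming chimeras and inverted
    end-duplication (fold-back) products, a read-pair classifier for the
    standard mapping QC taxonomy (proper pairs, singletons, interchromosomal,
    wrong-facing, same-orientation and incorrect-insert pairs, PCR
    duplicates), coverage evenness and windowed coverage profiling with
    repeat-content and GC-bias correlations, and replicate-based SNP fate
    classification for comparing variant calls between amplified and
    unamplified libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    VariantAnnotation,
    SummarizedExperiment,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
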