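Package: longasv
Title: Exact Amplicon Sequence Variants from Long-Read Amplicon Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers exact, chimera-free amplicon sequence variants (ASVs) of
    full-length marker genes (e.g. the ~1.5 kb 16S rRNA gene) from PacBio
    circular consensus (CCS) amplicon reads. Implements primer detection,
    orientation and removal for mixed-orientation CCS reads; quality filtering
    by expected errors; a quality-conditioned error model with separate
    estimation at the maximum quality score of 93; divisive-partitioning
    denoising with a kmer prefilter and banded Needleman-Wunsch alignment;
    de novo bimera detection with a parent-overabundance safeguard for
    multi-copy genes; mock-community evaluation analytics (genomic abundances,
    integral allele-ratio accuracy calls, raw-read error profiling,
    rarefaction, replicate concordance); strain-level binning of intragenomic
    alleles with full-complement consensus classification; and a synthetic
    CCS read simulator with known ground truth for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    dada2,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
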