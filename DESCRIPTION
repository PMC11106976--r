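Package: forkstall
Title: Replication Fork Stalling Hotspots from Multi-Timepoint BrdU-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of transient replication fork
    stalling/pausing hotspots from cell-cycle-staged BrdU-Seq coverage.
    Provides input-normalised Poisson peak calling with a local background,
    peak transience quantification across S-phase timepoints, classification
    of peaks by transcription-replication collision directionality
    (codirectional, head-on, undetermined), permutation statistics for
    overlap of peaks with structural-rearrangement breakpoints and fragile
    sites (difference-of-overlap-fraction statistic with Benjamini-Yekutieli
    correction, genome-shuffle empirical p-values, within-gene peak
    shuffling), metagene profiling including a ChIP density-decline
    replication-speed proxy, transcription elongation rate estimation from
    DRB-release pre-mRNA recovery timecourses, and a fully parameterised
    synthetic-data generator with ground-truth tables for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
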