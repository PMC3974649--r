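Package: gcrsig
Title: Detection and Classification of Gross Chromosomal Rearrangements in
    Yeast Chromosome V Marker-Loss Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing gross chromosomal rearrangements (GCRs)
    selected in Saccharomyces cerevisiae chromosome V marker-loss assays.
    Provides a synthetic-data generator that builds a model assay chromosome
    and constructs truth-labelled rearranged genomes by four mechanisms
    (interstitial deletion, fold-back inverted duplication, de novo telomere
    addition, translocation) together with paired-end read, aCGH, MLPA and
    fluctuation-assay simulators; a discordant read-pair junction caller with
    junction-read recruitment and consensus assembly; a junction annotator for
    breakpoint microhomology, fold-back hairpin geometry and telomere seeds;
    aCGH/MLPA copy-number interpretation; in-silico AscI/PFGE fragment
    analysis; an evidence-integrating GCR classifier; and the associated
    statistics (G-test of marker retention, Mann-Whitney rate comparisons,
    Lea-Coulson fluctuation-rate estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'assayChromosome.R'
    'rearrangements.R'
    'simulateReads.R'
    'junctionCaller.R'
    'junctionAnnotator.R'
    'simulateArrays.R'
    'copyNumber.R'
    'pfge.R'
    'classifier.R'
    'stats.R'
    'pipeline.R'
    'io.R'
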