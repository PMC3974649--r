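#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

.EVENT_CLASSES <- c("interstitial_deletion", "inverted_duplication",
                    "de_novo_telomere", "translocation")
.JUNCTION_CLASSES <- c("deletion", "translocation", "inversion_foldback",
                       "telomere_addition", "unresolved")
.GCR_CLASSES <- c(.EVENT_CLASSES, "complex", "unclassified")
.SIZE_CLASSES <- c("wild_type_like", "larger", "smaller")

## Names the assay layout must provide exactly once.
.REQUIRED_FEATURES <- c("TEL_L", "hph", "CAN1", "URA3",
                        "GCR_breakpoint_region", "PCM1", "ura3-52",
                        "MCM3", "CEN5", "TEL_R")

#' Model assay chromosome
#'
#' A synthetic chromosome V carrying the marker layout of the uGCR/dGCR
#' marker-loss assays: a telomeric \code{hph} hygromycin-resistance marker,
#' the \code{CAN1/URA3} counter-selectable cassette, the GCR breakpoint
#' region bounded by the cassette and the most telomeric essential gene
#' \code{PCM1}, a Ty-containing \code{ura3-52} allele, \code{CEN5}, AscI
#' restriction sites and a second \code{hph}-homologous tract internal to
#' the two AscI sites.
#'
#' @slot chromName single chromosome name.
#' @slot sequence \linkS4class{DNAString} of the chromosome.
#' @slot features \linkS4class{GRanges} of named feature intervals.
#' @exportClass AssayChromosome
setClass("AssayChromosome",
    representation(chromName = "character",
                   sequence = "DNAString",
                   features = "GRanges"))

setValidity("AssayChromosome", function(object) {
    msgs <- character(0)
    L <- length(object@sequence)
    feats <- object@features
    nm <- names(feats)
    if (is.null(nm) || any(nm == ""))
        return("all features must be named")
    if (any(GenomicRanges::start(feats) < 1L) ||
        any(GenomicRanges::end(feats) > L))
        msgs <- c(msgs, "feature intervals must lie within the chromosome")
    for (f in .REQUIRED_FEATURES)
        if (sum(nm == f) != 1L)
            msgs <- c(msgs, sprintf("feature '%s' must be present exactly once", f))
    if (sum(nm == "AscI") < 2L)
        msgs <- c(msgs, "at least two AscI sites are required")
    if (length(msgs) > 0L) return(msgs)
    pos <- function(f) GenomicRanges::start(feats)[nm == f][1L]
    cassStart <- min(pos("CAN1"), pos("URA3"))
    cassEnd <- max(pos("CAN1"), pos("URA3"))
    order_ok <- pos("TEL_L") < pos("hph") && pos("hph") < cassStart &&
        cassEnd < pos("GCR_breakpoint_region") &&
        pos("GCR_breakpoint_region") < pos("PCM1") &&
        pos("PCM1") < pos("ura3-52") && pos("ura3-52") < pos("CEN5")
    if (!order_ok)
        msgs <- c(msgs, paste("left-arm feature order must be TEL_L < hph <",
                              "CAN1/URA3 cassette < GCR_breakpoint_region <",
                              "PCM1 < ura3-52 < CEN5"))
    asc <- sort(GenomicRanges::start(feats)[nm == "AscI"])
    if (sum(nm == "hph_internal") != 1L) {
        msgs <- c(msgs, "an internal hph-homologous tract is required")
    } else {
        hi <- pos("hph_internal")
        if (!(hi > asc[1L] && hi < asc[length(asc)]))
            msgs <- c(msgs, "hph_internal must lie between the two AscI sites")
    }
    if (length(msgs) > 0L) msgs else TRUE
})

#' Truth record for a constructed rearrangement
#'
#' @slot eventClass one of interstitial_deletion, inverted_duplication,
#'   de_novo_telomere, translocation.
#' @slot coords named integer vector of 1-based breakpoint coordinates on the
#'   (edited) reference.
#' @slot microhomology bases of junction microhomology (deletions).
#' @slot primingHomology bases of fold-back priming homology (fold-backs only).
#' @slot loop unpaired hairpin loop length in bases (fold-backs only).
#' @slot resolution homology used to stabilise the product
#'   ("URA3/ura3-52", "Ty/Ty" or "none").
#' @slot insertSeq non-templated/donor sequence inserted at the junction.
#' @slot expectHph whether the product retains the hph marker.
#' @slot expectSizeClass expected PFGE size class of the product chromosome.
#' @exportClass RearrangementTruth
setClass("RearrangementTruth",
    representation(eventClass = "character",
                   coords = "integer",
                   microhomology = "integer",
                   primingHomology = "integer",
                   loop = "integer",
                   resolution = "character",
                   insertSeq = "character",
                   expectHph = "logical",
                   expectSizeClass = "character"))

setValidity("RearrangementTruth", function(object) {
    msgs <- character(0)
    if (!object@eventClass %in% .EVENT_CLASSES)
        msgs <- c(msgs, "unknown event class")
    fb <- object@eventClass == "inverted_duplication"
    if (fb && (is.na(object@loop) || is.na(object@primingHomology)))
        msgs <- c(msgs, "fold-back fields required for inverted duplications")
    if (!fb && !(is.na(object@loop) && is.na(object@primingHomology)))
        msgs <- c(msgs, "fold-back fields only allowed for inverted duplications")
    if (!object@expectSizeClass %in% .SIZE_CLASSES)
        msgs <- c(msgs, "unknown size class")
    if (length(msgs) > 0L) msgs else TRUE
})

#' Paired-end library model
#'
#' Parameters of the simulated sequencing library; the defaults emulate a
#' 600 bp gel-fractionated paired-end library.
#'
#' @slot insertMean,insertSd fragment-size distribution in bp.
#' @slot readLength read length in bp.
#' @slot coverage fold sequence coverage.
#' @slot dupFraction fraction of pairs that are exact duplicates.
#' @slot seed RNG seed.
#' @exportClass LibraryModel
setClass("LibraryModel",
    representation(insertMean = "numeric", insertSd = "numeric",
                   readLength = "integer", coverage = "numeric",
                   dupFraction = "numeric", seed = "integer"))

setValidity("LibraryModel", function(object) {
    msgs <- character(0)
    if (object@readLength > object@insertMean)
        msgs <- c(msgs, "read length must not exceed the insert mean")
    if (object@coverage <= 0)
        msgs <- c(msgs, "coverage must be positive")
    if (object@dupFraction < 0 || object@dupFraction >= 1)
        msgs <- c(msgs, "duplicate fraction must be in [0,1)")
    if (length(msgs) > 0L) msgs else TRUE
})

#' A rearranged isolate: product genome, edited reference, truth label
#'
#' The rearrangement constructors locally edit the reference (to plant
#' junction microhomology or hairpin priming homology) before building the
#' product, so both the product and the matching reference are returned.
#'
#' @slot product \linkS4class{DNAString} of the rearranged chromosome.
#' @slot reference the (possibly locally edited) \linkS4class{AssayChromosome}.
#' @slot truth the \linkS4class{RearrangementTruth} record.
#' @exportClass RearrangedIsolate
setClass("RearrangedIsolate",
    representation(product = "DNAString",
                   reference = "AssayChromosome",
                   truth = "RearrangementTruth"))

#' A clustered discordant-pair junction call
#'
#' @slot sideA,sideB \linkS4class{GRanges} giving the clustered mapped-mate
#'   interval and orientation on each side of the putative junction.
#' @slot geometry "cross" for convergent-inconsistent/distant pairs,
#'   "foldback" for same-orientation pairs on one target.
#' @slot supportIds ids of the supporting junction-defining pairs.
#' @slot support number of supporting pairs.
#' @slot pvalue Poisson p-value against the chimeric-pair background.
#' @slot significant significance flag.
#' @exportClass JunctionCall
setClass("JunctionCall",
    representation(sideA = "GRanges", sideB = "GRanges",
                   geometry = "character", supportIds = "character",
                   support = "integer", pvalue = "numeric",
                   significant = "logical"))

setValidity("JunctionCall", function(object) {
    if (object@support != length(object@supportIds))
        "support count must equal the number of supporting pair ids"
    else TRUE
})

#' Assembled junction consensus sequence
#'
#' @slot consensus consensus \linkS4class{DNAString}.
#' @slot nReads number of contributing junction-sequencing reads.
#' @slot agreement mean per-base agreement of the layout with the consensus.
#' @exportClass JunctionSequence
setClass("JunctionSequence",
    representation(consensus = "DNAString", nReads = "integer",
                   agreement = "numeric"))

setValidity("JunctionSequence", function(object) {
    if (object@nReads >= 1L && length(object@consensus) == 0L)
        "consensus must be non-empty when reads contributed"
    else TRUE
})

#' Breakpoint annotation of a junction consensus
#'
#' @slot sideA,sideB \linkS4class{GRanges} (width-1) breakpoint positions
#'   and strands on the reference; empty when unmappable.
#' @slot microhomology junction microhomology sequence ("" when none).
#' @slot insertSeq non-templated insert sequence ("" when none).
#' @slot junctionClass one of deletion, translocation, inversion_foldback,
#'   telomere_addition, unresolved.
#' @slot flags character notes (e.g. palindromic-flank cap).
#' @exportClass BreakpointAnnotation
setClass("BreakpointAnnotation",
    representation(sideA = "GRanges", sideB = "GRanges",
                   microhomology = "character", insertSeq = "character",
                   junctionClass = "character", flags = "character"))

setValidity("BreakpointAnnotation", function(object) {
    if (nchar(object@microhomology) > 0L && nchar(object@insertSeq) > 0L)
        "microhomology and non-templated insert are mutually exclusive"
    else TRUE
})

#' Fold-back (hairpin) geometry annotation
#'
#' @slot center reference coordinate of the loop-template midpoint.
#' @slot loopStart reference coordinate of the first loop-template base.
#' @slot primingHomology priming-homology sequence (inverted repeat flanking
#'   the loop, templated by the reference).
#' @slot loopSeq loop (unpaired spacer) sequence; may be "".
#' @exportClass FoldbackAnnotation
setClass("FoldbackAnnotation",
    representation(center = "integer", loopStart = "integer",
                   primingHomology = "character", loopSeq = "character"))

#' Final classification of one GCR isolate
#'
#' @slot isolate isolate id.
#' @slot gcrClass one of the four mechanistic classes, complex or
#'   unclassified.
#' @slot hphRetained whether the hph marker is retained.
#' @slot chrVLDuplication whether a chrV L duplication is present.
#' @slot resolution repeated feature stabilising the duplication, or "none".
#' @slot notes evidence notes.
#' @exportClass GCRClassification
setClass("GCRClassification",
    representation(isolate = "character", gcrClass = "character",
                   hphRetained = "logical", chrVLDuplication = "logical",
                   resolution = "character", notes = "character"))

setValidity("GCRClassification", function(object) {
    if (object@gcrClass == "inverted_duplication" && !object@chrVLDuplication)
        "inverted_duplication implies a chrV L duplication"
    else TRUE
})
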