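#' @include assayChromosome.R
NULL

## PFGE-style size class of a product chromosome relative to the reference.
sizeClassOf <- function(productLength, referenceLength, tolerance = 0.02) {
    d <- (productLength - referenceLength) / referenceLength
    if (abs(d) <= tolerance) "wild_type_like" else if (d > 0) "larger"
    else "smaller"
}

.refStr <- function(chrom) as.character(chromSequence(chrom))

.withSequence <- function(chrom, seq) {
    initialize(chrom, sequence = Biostrings::DNAString(seq))
}

.featSpan <- function(chrom, name) {
    r <- featureRange(chrom, name)[1L]
    c(GenomicRanges::start(r), GenomicRanges::end(r))
}

## Mutate position `at` of seq if it equals `forbidden` (guards that junction
## matches terminate exactly at the constructed breakpoints).
.guardBase <- function(seq, at, forbidden) {
    if (substr(seq, at, at) == forbidden)
        seq <- strAssign(seq, at, otherBase(forbidden))
    seq
}

.newIsolate <- function(product, chrom, truth) {
    new("RearrangedIsolate", product = Biostrings::DNAString(product),
        reference = chrom, truth = truth)
}

#' Apply an interstitial deletion spanning the CAN1/URA3 cassette
#'
#' Removes \code{[start, end]} (1-based, inclusive) from the assay
#' chromosome, optionally inserting a donor sequence at the junction.  The
#' deletion must overlap the \code{CAN1/URA3} cassette but leave \code{hph}
#' and the essential \code{PCM1} intact (events violating this are not
#' selectable in the assay).  When \code{microhomology > 0} the reference is
#' locally edited so that the retained flanks share exactly that many
#' identical terminal bases at the junction, with guard bases preventing any
#' longer accidental identity; truth labels are therefore deterministic.
#'
#' @param chrom an \linkS4class{AssayChromosome}.
#' @param start,end deleted interval, 1-based inclusive.
#' @param microhomology junction microhomology length in bases (0-10);
#'   must be 0 when \code{insert} is non-empty.
#' @param insert junction insert sequence (e.g. a Ty fragment), or \code{""}.
#' @return a \linkS4class{RearrangedIsolate}.
#' @export
applyInterstitialDeletion <- function(chrom, start, end,
                                      microhomology = 0L, insert = "") {
    stopifnot(is(chrom, "AssayChromosome"))
    start <- as.integer(start); end <- as.integer(end)
    m <- as.integer(microhomology)
    L <- chromLength(chrom)
    if (start >= end) stop("start must precede end")
    if (m < 0L || m > 10L) stop("microhomology must be in 0..10")
    if (nchar(insert) > 0L && m != 0L)
        stop("a junction insert and microhomology are mutually exclusive")
    cass <- range(c(.featSpan(chrom, "CAN1"), .featSpan(chrom, "URA3")))
    if (end < cass[1L] || start > cass[2L])
        stop("deletion must overlap the CAN1/URA3 cassette")
    for (f in c("hph", "PCM1")) {
        sp <- .featSpan(chrom, f)
        if (start <= sp[2L] && end >= sp[1L])
            stop("deletion removing ", f, " is not selectable in the assay")
    }
    if (start < 100L || end > L - 100L) stop("deletion too close to an end")

    seq <- .refStr(chrom)
    if (nchar(insert) == 0L) {
        if (m > 0L) {
            mhBases <- substr(seq, start - m, start - 1L)
            seq <- strAssign(seq, end - m + 1L, mhBases)
        }
        ## guards stop chance identity from extending the planted
        ## microhomology in either direction; guard positions lie inside
        ## the deleted interval, so the product is unaffected
        seq <- .guardBase(seq, end - m, substr(seq, start - m - 1L,
                                               start - m - 1L))
        seq <- .guardBase(seq, start, substr(seq, end + 1L, end + 1L))
    } else {
        insert <- toupper(insert)
        seq <- .guardBase(seq, start, substr(insert, 1L, 1L))
        seq <- .guardBase(seq, end, substr(insert, nchar(insert),
                                           nchar(insert)))
    }
    chrom <- .withSequence(chrom, seq)
    product <- paste0(substr(seq, 1L, start - 1L), insert,
                      substr(seq, end + 1L, nchar(seq)))

    truth <- new("RearrangementTruth",
        eventClass = "interstitial_deletion",
        coords = c(delStart = start, delEnd = end,
                   bpA = start - 1L, bpB = end + 1L),
        microhomology = m, primingHomology = NA_integer_,
        loop = NA_integer_, resolution = "none", insertSeq = insert,
        expectHph = TRUE,
        expectSizeClass = sizeClassOf(nchar(product), L))
    .newIsolate(product, chrom, truth)
}

#' Apply a fold-back inverted duplication
#'
#' Emulates hairpin-mediated inverted duplication: a DSB in the GCR
#' breakpoint region is resected, the single-stranded end folds back at a
#' short inverted repeat (the priming homology) leaving an unpaired loop,
#' and synthesis copies the chromosome centromerically up to a resolution
#' homology.  The product carries two inverted copies of the duplicated
#' segment separated by the single-copy loop; when the resolution homology
#' is \code{"URA3/ura3-52"} the hph-containing telomeric fragment is
#' recaptured through the cassette URA3 (hph retained), with \code{"Ty/Ty"}
#' a Ty-capped donor end is captured instead (hph lost), and with
#' \code{"none"} no telomeric fragment is captured (hph lost).
#'
#' The reference is locally edited to plant the priming-homology inverted
#' repeat telomeric of the loop (with a mismatch guard at length +1) and to
#' make the loop ends non-complementary, so hairpin geometry is recovered
#' exactly by annotation.
#'
#' @param chrom an \linkS4class{AssayChromosome}.
#' @param dsb double-strand-break position inside the GCR breakpoint region.
#' @param foldback first base of the hairpin loop template; must not be
#'   telomeric of the DSB.
#' @param loop unpaired loop length in bases (10-100; observed 25-44).
#' @param primingHomology priming inverted-repeat length (2-12; observed 3-9).
#' @param resolution \code{"URA3/ura3-52"}, \code{"Ty/Ty"} or \code{"none"}.
#' @return a \linkS4class{RearrangedIsolate}.
#' @export
applyInvertedDuplication <- function(chrom, dsb, foldback, loop,
                                     primingHomology,
                                     resolution = c("URA3/ura3-52", "Ty/Ty",
                                                    "none")) {
    stopifnot(is(chrom, "AssayChromosome"))
    resolution <- match.arg(resolution)
    dsb <- as.integer(dsb); lo <- as.integer(foldback)
    loop <- as.integer(loop); p <- as.integer(primingHomology)
    L <- chromLength(chrom)
    bk <- .featSpan(chrom, "GCR_breakpoint_region")
    if (dsb < bk[1L] || dsb > bk[2L])
        stop("dsb must lie inside the GCR breakpoint region")
    if (lo < dsb) stop("foldback must not be telomeric of the dsb")
    if (loop < 10L || loop > 100L) stop("loop must be in 10..100 bases")
    if (p < 2L || p > 12L) stop("priming homology must be in 2..12 bases")

    ura52 <- .featSpan(chrom, "ura3-52")
    coreLen <- nchar(markerTract("URA3_core"))
    tyLen <- nchar(markerTract("Ty"))
    tCore <- ura52[1L]                    # revcomp(URA3 core) tract start
    tTy <- ura52[1L] + coreLen            # revcomp(Ty consensus) tract start
    s <- lo + loop                        # first duplicated base
    anchor <- switch(resolution,
        "URA3/ura3-52" = tCore + coreLen %/% 2L - 1L,
        "Ty/Ty" = tTy + tyLen %/% 2L - 1L,
        "none" = tCore + coreLen %/% 2L - 1L)
    if (s >= anchor - 200L)
        stop("resolution feature is absent from the duplicated interval")

    seq <- .refStr(chrom)
    ## plant the priming inverted repeat telomeric of the loop
    armStart <- substr(seq, s, s + p - 1L)
    seq <- strAssign(seq, lo - p, revcompStr(armStart))
    seq <- .guardBase(seq, lo - p - 1L,
                      revcompStr(substr(seq, s + p, s + p)))
    ## loop ends must not be complementary (palindrome arms stop at the loop)
    loopSeq <- substr(seq, lo, s - 1L)
    if (substr(loopSeq, 1L, 1L) ==
        revcompStr(substr(loopSeq, loop, loop)))
        seq <- strAssign(seq, s - 1L,
                         otherBase(substr(seq, s - 1L, s - 1L)))
    chrom <- .withSequence(chrom, seq)

    invArm <- revcompStr(substr(seq, s, anchor))
    uCass <- .featSpan(chrom, "URA3")
    uCore <- uCass[1L] + 100L             # cassette URA3 core start
    capturedEnd <- NA_integer_
    captured <- ""
    if (resolution == "URA3/ura3-52") {
        capturedEnd <- uCore + coreLen %/% 2L - 1L
        captured <- substr(seq, 1L, capturedEnd)
    } else if (resolution == "Ty/Ty") {
        ## telomere-capped donor ending in the first half of the Ty consensus
        captured <- paste0(withSeed(7L, tgTract(120L, minWidth = 250L)),
                           substr(markerTract("Ty"), 1L, tyLen %/% 2L))
    }
    product <- paste0(captured, invArm, substr(seq, lo, L))

    delStart <- if (resolution == "URA3/ura3-52") capturedEnd + 1L else 1L
    truth <- new("RearrangementTruth",
        eventClass = "inverted_duplication",
        coords = c(dsb = dsb, loopStart = lo, armStart = s, anchor = anchor,
                   capturedEnd = capturedEnd, delStart = delStart,
                   delEnd = lo - 1L, dupStart = s, dupEnd = anchor),
        microhomology = NA_integer_, primingHomology = p, loop = loop,
        resolution = resolution, insertSeq = "",
        expectHph = resolution == "URA3/ura3-52",
        expectSizeClass = sizeClassOf(nchar(product), L))
    .newIsolate(product, chrom, truth)
}

#' Apply a de novo telomere addition
#'
#' Heals a break inside the GCR breakpoint region by seeding an irregular
#' TG1-3 telomeric tract at the new end; everything telomeric of \code{pos}
#' (including \code{hph} and the cassette) is lost.
#'
#' @param chrom an \linkS4class{AssayChromosome}.
#' @param pos first retained reference base.
#' @param seedRepeats number of TG1-3 repeat units in the seed tract
#'   (must be >= 8 so the tract is detectable over >= 15 nt).
#' @return a \linkS4class{RearrangedIsolate}.
#' @export
applyDeNovoTelomere <- function(chrom, pos, seedRepeats = 25L) {
    stopifnot(is(chrom, "AssayChromosome"))
    pos <- as.integer(pos); seedRepeats <- as.integer(seedRepeats)
    if (seedRepeats < 1L) stop("seedRepeats must be a positive integer")
    bk <- .featSpan(chrom, "GCR_breakpoint_region")
    cass <- range(c(.featSpan(chrom, "CAN1"), .featSpan(chrom, "URA3")))
    if (pos <= cass[2L])
        stop("a breakpoint telomeric of the cassette would retain ",
             "CAN1/URA3 and is not selectable")
    if (pos < bk[1L] || pos > bk[2L])
        stop("pos must lie inside the GCR breakpoint region")
    L <- chromLength(chrom)
    tract <- withSeed(fanSeed(pos, 5L), tgTract(seedRepeats, minWidth = 15L))
    seq <- .refStr(chrom)
    ## seed tract ends in G; stop the mapped suffix exactly at pos
    seq <- .guardBase(seq, pos - 1L, substr(tract, nchar(tract),
                                            nchar(tract)))
    chrom <- .withSequence(chrom, seq)
    product <- paste0(tract, substr(seq, pos, L))
    truth <- new("RearrangementTruth",
        eventClass = "de_novo_telomere",
        coords = c(pos = pos, delStart = 1L, delEnd = pos - 1L),
        microhomology = NA_integer_, primingHomology = NA_integer_,
        loop = NA_integer_, resolution = "none", insertSeq = tract,
        expectHph = FALSE,
        expectSizeClass = sizeClassOf(nchar(product), L))
    .newIsolate(product, chrom, truth)
}

#' Apply a translocation capping the broken arm with a donor sequence
#'
#' As \code{\link{applyDeNovoTelomere}} but the new telomeric side is an
#' arbitrary donor sequence (for example a copy of a centromeric reference
#' segment, or a Ty-carrying fragment).
#'
#' @param chrom an \linkS4class{AssayChromosome}.
#' @param pos first retained reference base (inside the breakpoint region).
#' @param donor donor nucleotide sequence (non-empty).
#' @param donorLabel text label recorded in the truth.
#' @param donorCoords optional 1-based reference interval the donor was
#'   copied from (for truth-checking), or NULL.
#' @return a \linkS4class{RearrangedIsolate}.
#' @export
applyTranslocation <- function(chrom, pos, donor, donorLabel = "donor",
                               donorCoords = NULL) {
    stopifnot(is(chrom, "AssayChromosome"))
    pos <- as.integer(pos)
    donor <- toupper(donor)
    if (nchar(donor) == 0L) stop("donor sequence must be non-empty")
    bk <- .featSpan(chrom, "GCR_breakpoint_region")
    cass <- range(c(.featSpan(chrom, "CAN1"), .featSpan(chrom, "URA3")))
    if (pos <= cass[2L])
        stop("a breakpoint telomeric of the cassette would retain ",
             "CAN1/URA3 and is not selectable")
    if (pos < bk[1L] || pos > bk[2L])
        stop("pos must lie inside the GCR breakpoint region")
    L <- chromLength(chrom)
    seq <- .refStr(chrom)
    seq <- .guardBase(seq, pos - 1L,
                      substr(donor, nchar(donor), nchar(donor)))
    ## when the donor is a reference copy, stop the junction prefix match
    ## exactly at the donor end (the retained base is edited consistently
    ## in reference and product)
    if (!is.null(donorCoords) && donorCoords[2L] < L)
        seq <- .guardBase(seq, pos,
                          substr(seq, donorCoords[2L] + 1L,
                                 donorCoords[2L] + 1L))
    chrom <- .withSequence(chrom, seq)
    product <- paste0(donor, substr(seq, pos, L))
    coords <- c(pos = pos, delStart = 1L, delEnd = pos - 1L)
    if (!is.null(donorCoords))
        coords <- c(coords, donorStart = as.integer(donorCoords[1L]),
                    donorEnd = as.integer(donorCoords[2L]))
    truth <- new("RearrangementTruth",
        eventClass = "translocation", coords = coords,
        microhomology = NA_integer_, primingHomology = NA_integer_,
        loop = NA_integer_, resolution = donorLabel, insertSeq = donor,
        expectHph = FALSE,
        expectSizeClass = sizeClassOf(nchar(product), L))
    .newIsolate(product, chrom, truth)
}

#' Per-base copy number of the reference implied by a truth record
#'
#' Interval accounting over the (edited) reference: deleted intervals drop
#' to 0 copies, duplicated intervals rise to 2, everything else is 1.
#'
#' @param truth a \linkS4class{RearrangementTruth}.
#' @param referenceLength reference length in bp.
#' @return an integer vector of per-base copy number.
#' @export
truthCopyNumber <- function(truth, referenceLength) {
    stopifnot(is(truth, "RearrangementTruth"))
    cn <- rep.int(1L, referenceLength)
    co <- truth@coords
    if (!is.na(co["delStart"]) && co["delEnd"] >= co["delStart"])
        cn[co["delStart"]:co["delEnd"]] <- 0L
    if (truth@eventClass == "inverted_duplication")
        cn[co["dupStart"]:co["dupEnd"]] <- cn[co["dupStart"]:co["dupEnd"]] + 1L
    cn
}
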