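#' @include junctionCaller.R
NULL

## Maximal exact affix (prefix or suffix) match of a consensus against the
## reference, either strand.  Anchored by a minAnchor-base probe; all probe
## hits are extended and the longest extension wins ('+' preferred on ties).
## Returns NULL when no extension reaches minAnchor bases.
.affixMatch <- function(cons, refSeq, type = c("prefix", "suffix"),
                        minAnchor = 15L) {
    type <- match.arg(type)
    n <- nchar(cons)
    L <- length(refSeq)
    if (n < minAnchor) return(NULL)
    refF <- as.character(refSeq)
    refR <- revcompStr(refF)
    probe <- if (type == "prefix") substr(cons, 1L, minAnchor)
             else substr(cons, n - minAnchor + 1L, n)
    best <- NULL
    for (strand in c("+", "-")) {
        ref <- if (strand == "+") refF else refR
        hits <- Biostrings::start(Biostrings::matchPattern(
            Biostrings::DNAString(probe), Biostrings::DNAString(ref)))
        for (st in hits) {
            if (type == "prefix") {
                ext <- lcpLength(cons, substr(ref, st, st + n - 1L))
                lastIdx <- st + ext - 1L       # working-strand coord
            } else {
                endIdx <- st + minAnchor - 1L
                lo <- max(1L, endIdx - n + 1L)
                ext <- lcsLength(cons, substr(ref, lo, endIdx))
                lastIdx <- endIdx
            }
            if (ext < minAnchor) next
            if (is.null(best) || ext > best$ext) {
                ## transform working-strand coords to forward-ref coords
                toRef <- function(i) if (strand == "+") i else L - i + 1L
                if (type == "prefix") {
                    best <- list(ext = ext, strand = strand,
                                 consStart = 1L, consEnd = ext,
                                 refAtConsEnd = toRef(lastIdx),
                                 refAtConsStart = toRef(st))
                } else {
                    best <- list(ext = ext, strand = strand,
                                 consStart = n - ext + 1L, consEnd = n,
                                 refAtConsStart = toRef(lastIdx - ext + 1L),
                                 refAtConsEnd = toRef(lastIdx))
                }
            }
        }
    }
    best
}

.sideGRanges <- function(rname, coord, strand, consIdx) {
    gr <- GenomicRanges::GRanges(rname, IRanges::IRanges(coord, coord),
                                 strand = strand)
    S4Vectors::mcols(gr)$consIdx <- consIdx
    gr
}

#' Place a junction consensus on the reference
#'
#' Finds the maximal exact prefix match and maximal exact suffix match of
#' the consensus against the reference (either strand).  The overlap of the
#' two matched intervals on the consensus is the junction microhomology; a
#' gap between them is the non-templated insert (mutually exclusive: when a
#' split is ambiguous the microhomology description is preferred and the
#' insert reported empty).  Side A is reported at the last prefix-matched
#' base and side B at the first suffix-matched base advanced past the
#' microhomology, so for a simple deletion the two sides are the last and
#' first retained reference bases.  A side whose match is shorter than
#' \code{minAnchor} exact bases is unmappable and the junction class is
#' \code{unresolved}.
#'
#' @param consensus a \linkS4class{JunctionSequence}, \code{DNAString} or
#'   character consensus (>= 40 bases).
#' @param reference an \linkS4class{AssayChromosome}.
#' @param minAnchor minimum exact match for a mappable side.
#' @return a \linkS4class{BreakpointAnnotation}; the side ranges carry the
#'   consensus index of the breakpoint base in \code{mcols(.)$consIdx}.
#' @export
locateJunction <- function(consensus, reference, minAnchor = 15L) {
    cons <- if (is(consensus, "JunctionSequence")) consensusSeq(consensus)
            else as.character(consensus)
    if (nchar(cons) < 40L) stop("consensus must be at least 40 bases")
    stopifnot(is(reference, "AssayChromosome"))
    refSeq <- chromSequence(reference)
    rn <- chromName(reference)
    pre <- .affixMatch(cons, refSeq, "prefix", minAnchor)
    suf <- .affixMatch(cons, refSeq, "suffix", minAnchor)
    emptyGr <- GenomicRanges::GRanges()

    if (is.null(pre) || is.null(suf)) {
        sideA <- if (is.null(pre)) emptyGr else
            .sideGRanges(rn, pre$refAtConsEnd, pre$strand, pre$consEnd)
        sideB <- if (is.null(suf)) emptyGr else
            .sideGRanges(rn, suf$refAtConsStart, suf$strand, suf$consStart)
        return(new("BreakpointAnnotation", sideA = sideA, sideB = sideB,
                   microhomology = "", insertSeq = "",
                   junctionClass = "unresolved", flags = character(0)))
    }

    mh <- ""
    ins <- ""
    flags <- character(0)
    overlap <- pre$consEnd - suf$consStart + 1L
    if (overlap > 0L) {
        mh <- substr(cons, suf$consStart, pre$consEnd)
    } else if (overlap < 0L) {
        ins <- substr(cons, pre$consEnd + 1L, suf$consStart - 1L)
    }
    mhLen <- nchar(mh)
    ## side B advanced past the microhomology along its own strand
    bCoord <- suf$refAtConsStart +
        (if (suf$strand == "+") mhLen else -mhLen)
    sideA <- .sideGRanges(rn, pre$refAtConsEnd, pre$strand, pre$consEnd)
    sideB <- .sideGRanges(rn, bCoord, suf$strand, suf$consStart + mhLen)

    cls <- if (pre$strand == suf$strand &&
               ((pre$strand == "+" && bCoord > pre$refAtConsEnd) ||
                (pre$strand == "-" && bCoord < pre$refAtConsEnd)))
        "deletion" else "translocation"
    new("BreakpointAnnotation", sideA = sideA, sideB = sideB,
        microhomology = mh, insertSeq = ins, junctionClass = cls,
        flags = flags)
}

#' Microhomology across a candidate junction split
#'
#' Given equal-length sequence windows from the two joined targets aligned
#' at a split point, counts the maximal run of identical bases contiguous
#' with (centred on) the split: bases matching immediately left of the
#' split plus bases matching from the split rightwards.  This is the
#' colon-notation identity of junction reports.  When a window is exhausted
#' the length is capped at the shorter flank and flagged.
#'
#' @param aSeq,bSeq equal-length windows from targets A and B.
#' @param split index of the first base right of the split (2..nchar).
#' @return list with \code{length}, \code{sequence} and \code{capped}.
#' @export
computeMicrohomology <- function(aSeq, bSeq, split) {
    stopifnot(nchar(aSeq) == nchar(bSeq))
    n <- nchar(aSeq)
    split <- as.integer(split)
    stopifnot(split >= 1L, split <= n + 1L)
    a <- strsplit(aSeq, "")[[1L]]
    b <- strsplit(bSeq, "")[[1L]]
    left <- 0L
    while (split - 1L - left >= 1L &&
           a[split - 1L - left] == b[split - 1L - left])
        left <- left + 1L
    right <- 0L
    while (split + right <= n && a[split + right] == b[split + right])
        right <- right + 1L
    capped <- (split - 1L - left < 1L) || (split + right > n)
    mh <- if (left + right > 0L)
        paste(a[(split - left):(split + right - 1L)], collapse = "")
    else ""
    list(length = left + right, sequence = mh, capped = capped)
}

#' Detect fold-back (hairpin) geometry in a junction consensus
#'
#' Aligns the consensus to its own reverse complement to find the
#' inverted-repeat arms of a fold-back junction; the unpaired centre is the
#' hairpin loop.  The loop template is located on the reference and the
#' priming homology is the maximal inverted repeat immediately flanking the
#' loop that is templated by the reference (the homology that primed the
#' hairpin).  Detection is invariant under reverse-complementing the input.
#'
#' @param consensus a \linkS4class{JunctionSequence}, \code{DNAString} or
#'   character consensus.
#' @param reference an \linkS4class{AssayChromosome}.
#' @param minArm minimum palindrome arm length in bases.
#' @param maxLoop maximum loop length considered.
#' @return a \linkS4class{FoldbackAnnotation}, or \code{NULL} when no
#'   inverted repeat of at least \code{minArm} bases exists.
#' @export
detectFoldback <- function(consensus, reference, minArm = 15L,
                           maxLoop = 150L) {
    cons <- if (is(consensus, "JunctionSequence")) consensusSeq(consensus)
            else as.character(consensus)
    stopifnot(is(reference, "AssayChromosome"))
    refStr <- as.character(chromSequence(reference))
    L <- nchar(refStr)

    tryOrient <- function(cons) {
        pal <- Biostrings::findPalindromes(Biostrings::DNAString(cons),
                                           min.armlength = minArm,
                                           max.looplength = maxLoop)
        if (length(pal) == 0L) return(NULL)
        arms <- Biostrings::palindromeArmLength(pal)
        i <- which.max(arms)
        arm <- arms[i]
        palStart <- Biostrings::start(pal)[i]
        palEnd <- Biostrings::end(pal)[i]
        loopLen <- palEnd - palStart + 1L - 2L * arm
        loopSeq <- if (loopLen > 0L)
            substr(cons, palStart + arm, palEnd - arm) else ""
        ## anchor the centromeric (right) arm on the forward reference
        anchorLen <- min(30L, arm)
        anchor <- substr(cons, palEnd - arm + 1L,
                         palEnd - arm + anchorLen)
        hits <- Biostrings::start(Biostrings::matchPattern(
            Biostrings::DNAString(anchor), Biostrings::DNAString(refStr)))
        for (s0 in hits) {
            lo <- s0 - loopLen
            if (lo < 2L) next
            if (loopLen > 0L &&
                substr(refStr, lo, s0 - 1L) != loopSeq) next
            ## maximal reference-templated inverted repeat flanking the loop
            p <- 0L
            while (lo - 1L - p >= 1L && s0 + p <= L &&
                   substr(refStr, lo - 1L - p, lo - 1L - p) ==
                   revcompStr(substr(refStr, s0 + p, s0 + p)))
                p <- p + 1L
            primingSeq <- if (p > 0L)
                substr(refStr, lo - p, lo - 1L) else ""
            return(new("FoldbackAnnotation",
                       center = as.integer(lo + loopLen %/% 2L),
                       loopStart = as.integer(lo),
                       primingHomology = primingSeq,
                       loopSeq = loopSeq))
        }
        NULL
    }
    tryOrient(cons) %||% tryOrient(revcompStr(cons))
}

#' TG1-3 telomere-seed detection on an unmapped consensus tail
#'
#' Scores conformity to the irregular yeast telomeric repeat by greedy
#' tiling with TG/TGG/TGGG units; a tail of at least \code{minLength}
#' bases with conformity of at least \code{minConformity} is called a de
#' novo telomere seed.
#'
#' @param tail the unmapped tail sequence.
#' @param minLength minimum tail length in nt.
#' @param minConformity minimum fraction of bases covered by repeat units.
#' @return list with \code{detected}, \code{conformity} and \code{length}.
#' @export
detectTelomereAddition <- function(tail, minLength = 15L,
                                   minConformity = 0.9) {
    n <- nchar(tail)
    if (n == 0L)
        return(list(detected = FALSE, conformity = 0, length = 0L))
    covered <- 0L
    i <- 1L
    while (i <= n) {
        advanced <- FALSE
        for (unit in c("TGGG", "TGG", "TG")) {
            u <- nchar(unit)
            if (i + u - 1L <= n && substr(tail, i, i + u - 1L) == unit) {
                covered <- covered + u
                i <- i + u
                advanced <- TRUE
                break
            }
        }
        if (!advanced) i <- i + 1L
    }
    conf <- covered / n
    list(detected = n >= minLength && conf >= minConformity,
         conformity = conf, length = n)
}

#' Classify a junction from its annotations
#'
#' Priority order: telomere addition, then fold-back inversion, then
#' deletion (both sides on one target, same strand, side B centromeric of
#' side A), otherwise translocation; unresolved placements propagate.
#'
#' @param annotation a \linkS4class{BreakpointAnnotation}.
#' @param foldback a \linkS4class{FoldbackAnnotation} or \code{NULL}.
#' @param telomere a telomere call (list from
#'   \code{\link{detectTelomereAddition}}) or \code{NULL}.
#' @return junction class string.
#' @export
classifyJunction <- function(annotation, foldback = NULL, telomere = NULL) {
    stopifnot(is(annotation, "BreakpointAnnotation"))
    if (!is.null(telomere) && isTRUE(telomere$detected))
        return("telomere_addition")
    if (!is.null(foldback)) return("inversion_foldback")
    annotation@junctionClass
}

#' Annotate one junction consensus end-to-end
#'
#' Runs placement, fold-back detection and telomere-seed detection, and
#' returns the updated annotation together with the evidence objects.  A
#' side is considered solidly placed when its exact match extends at least
#' \code{minSideExt} bases; a short or absent placement whose consensus
#' tail conforms to the TG1-3 pattern is treated as a de novo telomere
#' seed (telomere seeds can match the reference telomere tracts weakly by
#' chance, so a short match does not veto telomere detection).
#'
#' @param consensus consensus sequence.
#' @param reference an \linkS4class{AssayChromosome}.
#' @param minSideExt minimum exact-match length of a solid side placement.
#' @return list with \code{annotation}, \code{foldback}, \code{telomere}.
#' @export
annotateJunction <- function(consensus, reference, minSideExt = 40L) {
    cons <- if (is(consensus, "JunctionSequence")) consensusSeq(consensus)
            else as.character(consensus)
    ann <- locateJunction(cons, reference)
    ## canonical orientation: assembly emits an arbitrary strand, so when
    ## every placed side maps to the minus strand the consensus is the
    ## reverse complement of the junction as drawn on the reference —
    ## re-annotate the flipped sequence so breakpoint and microhomology
    ## conventions are strand-independent
    strands <- c(if (length(ann@sideA) > 0L)
                     as.character(GenomicRanges::strand(ann@sideA)),
                 if (length(ann@sideB) > 0L)
                     as.character(GenomicRanges::strand(ann@sideB)))
    if (length(strands) > 0L && all(strands == "-")) {
        cons <- revcompStr(cons)
        ann <- locateJunction(cons, reference)
    }
    n <- nchar(cons)
    mhL <- nchar(ann@microhomology)
    aExt <- if (length(ann@sideA) > 0L)
        S4Vectors::mcols(ann@sideA)$consIdx else 0L
    bStart <- if (length(ann@sideB) > 0L)
        S4Vectors::mcols(ann@sideB)$consIdx - mhL else n + 1L
    bExt <- n - bStart + 1L

    fb <- NULL
    tel <- NULL
    if (aExt >= minSideExt && bExt >= minSideExt &&
        as.character(GenomicRanges::strand(ann@sideA)) !=
        as.character(GenomicRanges::strand(ann@sideB)))
        fb <- detectFoldback(cons, reference)
    if (is.null(fb)) {
        if (bExt >= minSideExt && aExt < minSideExt && bStart - 1L >= 1L)
            tel <- detectTelomereAddition(substr(cons, 1L, bStart - 1L))
        if ((is.null(tel) || !tel$detected) &&
            aExt >= minSideExt && bExt < minSideExt && aExt + 1L <= n)
            tel <- detectTelomereAddition(
                revcompStr(substr(cons, aExt + 1L, n)))
    }
    cls <- classifyJunction(ann, fb, tel)
    if (cls == ann@junctionClass &&
        (aExt < minSideExt || bExt < minSideExt))
        cls <- "unresolved"
    ann@junctionClass <- cls
    list(annotation = ann, foldback = fb, telomere = tel)
}

#' @rdname accessors
#' @export
setMethod("junctionClass", "BreakpointAnnotation",
          function(x) x@junctionClass)
#' @rdname accessors
#' @export
setMethod("microhomologySeq", "BreakpointAnnotation",
          function(x) x@microhomology)
#' @rdname accessors
#' @export
setMethod("loopLength", "FoldbackAnnotation",
          function(x) nchar(x@loopSeq))
#' @rdname accessors
#' @export
setMethod("primingHomologyLength", "FoldbackAnnotation",
          function(x) nchar(x@primingHomology))

setMethod("show", "BreakpointAnnotation", function(object) {
    fmt <- function(g) {
        if (length(g) == 0L) return("unmapped")
        sprintf("%s:%d(%s)", as.character(GenomicRanges::seqnames(g)),
                GenomicRanges::start(g),
                as.character(GenomicRanges::strand(g)))
    }
    cat(sprintf("BreakpointAnnotation [%s] %s | %s mh='%s' insert=%dnt\n",
                object@junctionClass, fmt(object@sideA), fmt(object@sideB),
                object@microhomology, nchar(object@insertSeq)))
})

setMethod("show", "FoldbackAnnotation", function(object) {
    cat(sprintf(
        "FoldbackAnnotation: center %d, loop %d nt, priming homology %d nt\n",
        object@center, nchar(object@loopSeq),
        nchar(object@primingHomology)))
})

#' Junction report in colon notation
#'
#' Human-readable junction alignment: the two target sequences above and
#' below the junction sequence, with the shared (microhomology) bases
#' delimited by colons.
#'
#' @param annotation a \linkS4class{BreakpointAnnotation}.
#' @param consensus the consensus the annotation was derived from.
#' @param reference the \linkS4class{AssayChromosome}.
#' @param flank flanking bases shown on each side.
#' @return character vector of report lines.
#' @export
junctionReport <- function(annotation, consensus, reference, flank = 30L) {
    cons <- if (is(consensus, "JunctionSequence")) consensusSeq(consensus)
            else as.character(consensus)
    mh <- annotation@microhomology
    aIdx <- if (length(annotation@sideA)) S4Vectors::mcols(
        annotation@sideA)$consIdx else NA_integer_
    bIdx <- if (length(annotation@sideB)) S4Vectors::mcols(
        annotation@sideB)$consIdx else NA_integer_
    mid <- if (nchar(mh) > 0L && !is.na(aIdx)) {
        lo <- max(1L, aIdx - nchar(mh) - flank + 1L)
        hi <- min(nchar(cons), aIdx + flank)
        paste0(substr(cons, lo, aIdx - nchar(mh)), ":", mh, ":",
               substr(cons, aIdx + 1L, hi))
    } else cons
    c(sprintf("junction class: %s", annotation@junctionClass),
      sprintf("side A: %s", if (is.na(aIdx)) "unmapped" else
          sprintf("%d(%s)", GenomicRanges::start(annotation@sideA),
                  as.character(GenomicRanges::strand(annotation@sideA)))),
      mid,
      sprintf("side B: %s", if (is.na(bIdx)) "unmapped" else
          sprintf("%d(%s)", GenomicRanges::start(annotation@sideB),
                  as.character(GenomicRanges::strand(annotation@sideB)))))
}
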