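#' @include simulateReads.R
NULL

#' Load mapped read pairs from SAM
#'
#' Ingests a paired SAM file (via Rsamtools) into the MappedPair table used
#' by the junction caller.  A read is treated as uniquely mapping when its
#' mapping quality is at least \code{mapqMin} and it is not a secondary
#' alignment.  Unpaired records are rejected with a reported count.
#'
#' @param samPath path to a SAM file with paired records.
#' @param mapqMin mapping-quality threshold for the uniqueness dialect.
#' @return a \code{data.frame} with one row per template and per-mate
#'   columns (rname, pos, strand, mapped, unique, seq).
#' @export
loadMappedPairs <- function(samPath, mapqMin = 20L) {
    if (!file.exists(samPath)) stop("no such SAM file: ", samPath)
    bam <- Rsamtools::asBam(samPath,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    on.exit(unlink(bam))
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "strand", "mapq",
                 "seq")))[[1L]]
    flag <- res$flag
    secondary <- bitwAnd(flag, 256L) > 0L
    keep <- !secondary
    paired <- bitwAnd(flag, 1L) > 0L
    nUnpaired <- sum(!paired & keep)
    if (nUnpaired > 0L)
        warning(nUnpaired, " unpaired records rejected")
    keep <- keep & paired
    first <- bitwAnd(flag, 64L) > 0L
    unmapped <- bitwAnd(flag, 4L) > 0L
    mk <- function(sel) {
        data.frame(qname = res$qname[sel],
                   rname = ifelse(unmapped[sel], NA_character_,
                                  as.character(res$rname[sel])),
                   pos = ifelse(unmapped[sel], NA_integer_, res$pos[sel]),
                   strand = ifelse(unmapped[sel], NA_character_,
                                   as.character(res$strand[sel])),
                   mapped = !unmapped[sel],
                   unique = !unmapped[sel] & res$mapq[sel] >= mapqMin,
                   seq = as.character(res$seq[sel]))
    }
    d1 <- mk(keep & first)
    d2 <- mk(keep & !first)
    names(d1)[-1L] <- paste0("r1_", names(d1)[-1L])
    names(d2)[-1L] <- paste0("r2_", names(d2)[-1L])
    dangling <- sum(!d1$qname %in% d2$qname) + sum(!d2$qname %in% d1$qname)
    if (dangling > 0L)
        warning(dangling, " records without a mate rejected")
    out <- merge(d1, d2, by = "qname", sort = FALSE)
    if (nrow(out) == 0L) warning("no read pairs loaded from ", samPath)
    out[order(out$qname), , drop = FALSE]
}

#' Remove PCR/optical duplicate pairs
#'
#' Among pairs sharing both mates' (target, start, orientation) — or, for
#' mates without coordinates, the read sequence — exactly one
#' representative (the first encountered) is retained.  Idempotent.
#'
#' @param pairs a MappedPair \code{data.frame}.
#' @return the deduplicated \code{data.frame}.
#' @export
deduplicatePairs <- function(pairs) {
    if (nrow(pairs) == 0L) return(pairs)
    keyOf <- function(p) {
        g <- function(col) pairs[[paste0(p, "_", col)]]
        ifelse(g("mapped"),
               paste(g("rname"), g("pos"), g("strand"), sep = ":"),
               paste0("seq:", g("seq")))
    }
    key <- paste(keyOf("r1"), keyOf("r2"), sep = "|")
    pairs[!duplicated(key), , drop = FALSE]
}

#' Per-base nread and nspan coverage tracks
#'
#' For pairs with both mates uniquely mapped, \code{nread} counts how many
#' times each base was read and \code{nspan} how many times each base was
#' spanned by a pair (the closed interval between the outermost mapped
#' bases).
#'
#' @param pairs a deduplicated MappedPair \code{data.frame}.
#' @param targetLength length of the target chromosome.
#' @param readLength read length in bp.
#' @return a list with integer vectors \code{nread} and \code{nspan}.
#' @export
computeCoverageTracks <- function(pairs, targetLength,
                                  readLength = nchar(pairs$r1_seq[1L])) {
    use <- pairs$r1_unique & pairs$r2_unique
    p <- pairs[use, , drop = FALSE]
    reads <- IRanges::IRanges(
        start = c(p$r1_pos, p$r2_pos),
        width = readLength)
    lo <- pmin(p$r1_pos, p$r2_pos)
    hi <- pmax(p$r1_pos, p$r2_pos) + readLength - 1L
    spans <- IRanges::IRanges(start = lo, end = hi)
    clip <- function(x) IRanges::restrict(x, start = 1L,
                                          end = as.integer(targetLength))
    list(nread = as.integer(IRanges::coverage(clip(reads),
                                              width = targetLength)),
         nspan = as.integer(IRanges::coverage(clip(spans),
                                              width = targetLength)))
}

#' Estimate the insert-size distribution and concordance cutoff
#'
#' Uses pairs with both mates uniquely mapped on one target in convergent
#' orientation.  The mapped inter-read distance is the outer span of the
#' pair; the concordance cutoff is \code{median + k * MAD}.
#'
#' @param pairs a MappedPair \code{data.frame}.
#' @param k cutoff multiplier (default 10 MADs above the median).
#' @param readLength read length in bp.
#' @param minPairs minimum usable pairs.
#' @return a list (class \code{InsertStats}) with \code{median}, \code{mad},
#'   \code{cutoff} and \code{nPairs}.
#' @export
estimateInsertStats <- function(pairs, k = 10,
                                readLength = nchar(pairs$r1_seq[1L]),
                                minPairs = 100L) {
    use <- pairs$r1_unique & pairs$r2_unique &
        pairs$r1_rname == pairs$r2_rname &
        pairs$r1_strand != pairs$r2_strand
    p <- pairs[which(use), , drop = FALSE]
    ## convergent: the forward mate is the leftmost
    fwdPos <- ifelse(p$r1_strand == "+", p$r1_pos, p$r2_pos)
    revPos <- ifelse(p$r1_strand == "+", p$r2_pos, p$r1_pos)
    p <- p[fwdPos <= revPos, , drop = FALSE]
    dist <- abs(pmax(p$r1_pos, p$r2_pos) + readLength - 1L -
                pmin(p$r1_pos, p$r2_pos)) + 1L
    if (length(dist) < minPairs)
        stop("too few convergent uniquely-mapped pairs (", length(dist),
             "); supply an explicit concordance cutoff")
    med <- median(dist)
    md <- mad(dist)
    structure(list(median = med, mad = md, cutoff = med + k * md,
                   nPairs = length(dist)),
              class = "InsertStats")
}

#' @export
print.InsertStats <- function(x, ...) {
    cat(sprintf(
        "InsertStats: median %.0f bp, MAD %.1f, cutoff %.0f (%d pairs)\n",
        x$median, x$mad, x$cutoff, x$nPairs))
    invisible(x)
}

## Is a both-mates-unique pair concordant with the reference?
.isConcordant <- function(pairs, cutoff, readLength) {
    sameTarget <- pairs$r1_rname == pairs$r2_rname
    opp <- pairs$r1_strand != pairs$r2_strand
    fwdPos <- ifelse(pairs$r1_strand == "+", pairs$r1_pos, pairs$r2_pos)
    revPos <- ifelse(pairs$r1_strand == "+", pairs$r2_pos, pairs$r1_pos)
    span <- abs(pmax(pairs$r1_pos, pairs$r2_pos) + readLength - 1L -
                pmin(pairs$r1_pos, pairs$r2_pos)) + 1L
    sameTarget & opp & fwdPos <= revPos & span <= cutoff
}

#' Cluster junction-defining read pairs into junction calls
#'
#' Pairs with both mates uniquely mapped whose geometry is inconsistent
#' with the reference (inter-read distance beyond the concordance cutoff,
#' non-convergent orientation, or different targets) are junction-defining.
#' They are clustered greedily in coordinate order: a pair joins a cluster
#' iff on both sides the orientations match and start coordinates lie
#' within the cutoff.  Fold-back geometry (both sides on one target with
#' the same orientation) is retained as a distinct call geometry with its
#' own lower support floor, because read-pair yield over palindromes is
#' reduced.  Cluster significance is a Poisson test of the support count
#' against a genome-wide chimeric-pair background rate.
#'
#' @param pairs a deduplicated MappedPair \code{data.frame}.
#' @param stats an \code{InsertStats} object (or a list with \code{cutoff}).
#' @param minSupport support floor for cross junction calls.
#' @param minSupportFoldback support floor for fold-back geometry calls.
#' @param alpha significance level of the Poisson background test.
#' @param targetLength target length (for the background rate).
#' @return a list of \linkS4class{JunctionCall} objects.
#' @export
clusterJunctionPairs <- function(pairs, stats, minSupport = 3L,
                                 minSupportFoldback = 2L, alpha = 0.01,
                                 targetLength = NULL) {
    rl <- nchar(pairs$r1_seq[1L])
    cutoff <- stats$cutoff
    use <- which(pairs$r1_unique & pairs$r2_unique)
    p <- pairs[use, , drop = FALSE]
    conc <- .isConcordant(p, cutoff, rl)
    disc <- p[!conc, , drop = FALSE]
    if (nrow(disc) == 0L) return(list())
    if (is.null(targetLength))
        targetLength <- max(c(disc$r1_pos, disc$r2_pos)) + rl

    ## canonical side order: side A is the lexicographically smaller locus
    swap <- disc$r1_rname > disc$r2_rname |
        (disc$r1_rname == disc$r2_rname & disc$r1_pos > disc$r2_pos)
    side <- function(colA, colB) ifelse(swap, disc[[colB]], disc[[colA]])
    d <- data.frame(qname = disc$qname,
                    a_rname = side("r1_rname", "r2_rname"),
                    a_pos = side("r1_pos", "r2_pos"),
                    a_strand = side("r1_strand", "r2_strand"),
                    b_rname = side("r2_rname", "r1_rname"),
                    b_pos = side("r2_pos", "r1_pos"),
                    b_strand = side("r2_strand", "r1_strand"))
    d <- d[order(d$a_rname, d$a_pos, d$b_pos), , drop = FALSE]

    clusters <- list()
    for (i in seq_len(nrow(d))) {
        placed <- FALSE
        for (j in seq_along(clusters)) {
            cl <- clusters[[j]]
            if (d$a_rname[i] == cl$a_rname && d$b_rname[i] == cl$b_rname &&
                d$a_strand[i] == cl$a_strand &&
                d$b_strand[i] == cl$b_strand &&
                d$a_pos[i] >= cl$a_min - cutoff &&
                d$a_pos[i] <= cl$a_max + cutoff &&
                d$b_pos[i] >= cl$b_min - cutoff &&
                d$b_pos[i] <= cl$b_max + cutoff) {
                cl$rows <- c(cl$rows, i)
                cl$a_min <- min(cl$a_min, d$a_pos[i])
                cl$a_max <- max(cl$a_max, d$a_pos[i])
                cl$b_min <- min(cl$b_min, d$b_pos[i])
                cl$b_max <- max(cl$b_max, d$b_pos[i])
                clusters[[j]] <- cl
                placed <- TRUE
                break
            }
        }
        if (!placed)
            clusters[[length(clusters) + 1L]] <- list(
                rows = i, a_rname = d$a_rname[i], b_rname = d$b_rname[i],
                a_strand = d$a_strand[i], b_strand = d$b_strand[i],
                a_min = d$a_pos[i], a_max = d$a_pos[i],
                b_min = d$b_pos[i], b_max = d$b_pos[i])
    }

    bgRate <- nrow(d) / targetLength            # chimeric pairs per bp
    lambda <- bgRate * 2 * cutoff
    out <- lapply(clusters, function(cl) {
        support <- length(cl$rows)
        geometry <- if (cl$a_rname == cl$b_rname &&
                        cl$a_strand == cl$b_strand) "foldback" else "cross"
        floorN <- if (geometry == "foldback") minSupportFoldback
                  else minSupport
        pval <- ppois(support - 1L, lambda, lower.tail = FALSE)
        gr <- function(rname, lo, hi, strand)
            GenomicRanges::GRanges(rname,
                                   IRanges::IRanges(lo, hi + rl - 1L),
                                   strand = strand)
        new("JunctionCall",
            sideA = gr(cl$a_rname, cl$a_min, cl$a_max, cl$a_strand),
            sideB = gr(cl$b_rname, cl$b_min, cl$b_max, cl$b_strand),
            geometry = geometry,
            supportIds = d$qname[cl$rows],
            support = support,
            pvalue = pval,
            significant = support >= floorN && pval <= alpha)
    })
    ord <- order(vapply(out, function(x) x@support, integer(1)),
                 decreasing = TRUE)
    out[ord]
}

#' @rdname accessors
#' @export
setMethod("supportCount", "JunctionCall", function(x) x@support)
#' @rdname accessors
#' @export
setMethod("isSignificant", "JunctionCall", function(x) x@significant)

setMethod("show", "JunctionCall", function(object) {
    fmt <- function(g) sprintf("%s:%d-%d(%s)",
                               as.character(GenomicRanges::seqnames(g)),
                               GenomicRanges::start(g),
                               GenomicRanges::end(g),
                               as.character(GenomicRanges::strand(g)))
    cat(sprintf(
        "JunctionCall [%s] %s | %s support=%d p=%.3g%s\n",
        object@geometry, fmt(object@sideA), fmt(object@sideB),
        object@support, object@pvalue,
        if (object@significant) " *" else ""))
})

#' Recruit junction-sequencing reads for a call
#'
#' Returns the unmapped mates of pairs whose mapped mate lies within one
#' concordance cutoff of either side interval of the call and matches that
#' side's orientation; these reads sequence across the junction itself.
#'
#' @param call a \linkS4class{JunctionCall}, or \code{NULL} to anchor at an
#'   explicit interval via \code{anchor}.
#' @param pairs a deduplicated MappedPair \code{data.frame}.
#' @param stats an \code{InsertStats} object.
#' @param anchor optional \linkS4class{GRanges} anchor used instead of the
#'   call sides (one-sided recruitment, e.g. at a terminal-deletion
#'   boundary); strand "*" accepts either orientation.
#' @return character vector of recruited read sequences (as sequenced).
#' @export
recruitJunctionReads <- function(call, pairs, stats, anchor = NULL) {
    cutoff <- stats$cutoff
    sides <- if (!is.null(anchor)) list(anchor)
             else list(call@sideA, call@sideB)
    half1 <- pairs$r1_unique & !pairs$r2_mapped
    half2 <- pairs$r2_unique & !pairs$r1_mapped
    hits <- character(0)
    for (side in sides) {
        lo <- GenomicRanges::start(side) - cutoff
        hi <- GenomicRanges::end(side) + cutoff
        str <- as.character(GenomicRanges::strand(side))
        rn <- as.character(GenomicRanges::seqnames(side))
        ok1 <- half1 & pairs$r1_rname == rn & pairs$r1_pos >= lo &
            pairs$r1_pos <= hi &
            (str == "*" | pairs$r1_strand == str)
        ok2 <- half2 & pairs$r2_rname == rn & pairs$r2_pos >= lo &
            pairs$r2_pos <= hi &
            (str == "*" | pairs$r2_strand == str)
        hits <- c(hits, pairs$r2_seq[which(ok1)], pairs$r1_seq[which(ok2)])
    }
    unique(hits)
}

#' Assemble a junction consensus from junction-sequencing reads
#'
#' Greedy overlap-layout assembly with exact-match overlaps of at least
#' \code{minOverlap} bases (reads are tried in both orientations), followed
#' by per-column majority consensus; ties are broken lexicographically and
#' reflected in the per-base agreement.  Reads that cannot be joined leave
#' the largest layout with a multiple-contig warning.
#'
#' @param reads character vector (or \code{DNAStringSet}) of reads.
#' @param minOverlap minimum exact overlap in bases.
#' @return a \linkS4class{JunctionSequence}.
#' @export
assembleJunctionConsensus <- function(reads, minOverlap = 20L) {
    if (is(reads, "DNAStringSet")) reads <- as.character(reads)
    reads <- unname(reads)
    if (length(reads) == 0L) stop("at least one read is required")
    reads <- reads[order(nchar(reads), reads, decreasing = TRUE)]

    ## layout: contig string plus per-read offsets into it
    contig <- reads[1L]
    layout <- list(list(seq = reads[1L], offset = 1L))
    remaining <- reads[-1L]

    bestOverlap <- function(contig, read) {
        ## returns list(type, len, offset) for the best exact join of `read`
        ## (already oriented) onto `contig`
        idx <- regexpr(read, contig, fixed = TRUE)
        if (idx > 0L)
            return(list(type = "contained", len = nchar(read),
                        offset = as.integer(idx)))
        maxk <- min(nchar(contig), nchar(read)) - 1L
        if (maxk < minOverlap) return(NULL)
        for (k in seq(maxk, minOverlap, by = -1L)) {
            ## read extends right: contig suffix == read prefix
            if (substr(contig, nchar(contig) - k + 1L, nchar(contig)) ==
                substr(read, 1L, k))
                return(list(type = "right", len = k,
                            offset = nchar(contig) - k + 1L))
            ## read extends left: read suffix == contig prefix
            if (substr(read, nchar(read) - k + 1L, nchar(read)) ==
                substr(contig, 1L, k))
                return(list(type = "left", len = k,
                            offset = 1L - (nchar(read) - k)))
        }
        NULL
    }

    repeat {
        if (length(remaining) == 0L) break
        best <- NULL; bestI <- 0L; bestSeq <- NULL
        for (i in seq_along(remaining)) {
            for (s in c(remaining[i], revcompStr(remaining[i]))) {
                ov <- bestOverlap(contig, s)
                if (!is.null(ov) &&
                    (is.null(best) || ov$len > best$len ||
                     (ov$len == best$len && s < bestSeq))) {
                    best <- ov; bestI <- i; bestSeq <- s
                }
            }
        }
        if (is.null(best)) break
        if (best$type == "right") {
            contig <- paste0(contig,
                             substr(bestSeq, best$len + 1L, nchar(bestSeq)))
        } else if (best$type == "left") {
            shift <- nchar(bestSeq) - best$len
            contig <- paste0(substr(bestSeq, 1L, shift), contig)
            layout <- lapply(layout, function(x) {
                x$offset <- x$offset + shift; x })
            best$offset <- 1L
        }
        layout[[length(layout) + 1L]] <- list(seq = bestSeq,
                                              offset = best$offset)
        remaining <- remaining[-bestI]
    }
    if (length(remaining) > 0L)
        warning(length(remaining), " reads could not be joined; ",
                "emitting the largest layout")

    ## per-column majority consensus over the layout
    n <- nchar(contig)
    counts <- matrix(0L, nrow = 4L, ncol = n,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    for (x in layout) {
        chars <- strsplit(x$seq, "")[[1L]]
        cols <- x$offset + seq_along(chars) - 1L
        for (i in seq_along(chars))
            counts[chars[i], cols[i]] <- counts[chars[i], cols[i]] + 1L
    }
    tot <- colSums(counts)
    winners <- apply(counts, 2L, function(col) {
        w <- which(col == max(col))
        rownames(counts)[w[1L]]          # lexicographic tie-break
    })
    consensus <- paste(winners, collapse = "")
    agree <- sum(counts[cbind(match(winners, rownames(counts)),
                              seq_len(n))]) / sum(tot)
    new("JunctionSequence", consensus = Biostrings::DNAString(consensus),
        nReads = length(layout), agreement = agree)
}

#' @rdname accessors
#' @export
setMethod("consensusSeq", "JunctionSequence",
          function(x) as.character(x@consensus))

setMethod("show", "JunctionSequence", function(object) {
    cat(sprintf("JunctionSequence: %d bp from %d reads (agreement %.3f)\n",
                length(object@consensus), object@nReads, object@agreement))
})
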