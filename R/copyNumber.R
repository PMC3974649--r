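#' @include simulateArrays.R
NULL

#' Segment an aCGH log2 track into copy-state intervals
#'
#' Probes are classified as duplicated, neutral or deleted by thresholds
#' (haploid semantics: a duplication sits at log2 +1 and a deletion at the
#' track floor, so the defaults are placed midway between states), merged
#' into runs, and runs shorter than \code{minProbes} are absorbed into the
#' larger neighbouring run.  Segment boundaries are placed at the midpoint
#' between the last probe of one state and the first probe of the next.
#'
#' @param track probe \code{data.frame} with columns start, end, log2,
#'   coordinate-sorted.
#' @param dupThreshold log2 at or above which a probe is duplicated.
#' @param delThreshold log2 at or below which a probe is deleted.
#' @param minProbes minimum probes per non-neutral segment.
#' @param chromName chromosome name for the output ranges.
#' @return a \linkS4class{GRanges} of segments with metadata columns
#'   \code{state}, \code{meanLog2} and \code{nProbes}.
#' @export
segmentLog2Track <- function(track, dupThreshold = 0.58,
                             delThreshold = -1.0, minProbes = 3L,
                             chromName = "assay_chrV") {
    if (nrow(track) == 0L) stop("empty probe track")
    if (is.unsorted(track$start))
        stop("probes must be coordinate-sorted")
    state <- ifelse(track$log2 >= dupThreshold, "duplicated",
                    ifelse(track$log2 <= delThreshold, "deleted",
                           "neutral"))
    ## absorb short runs into the larger neighbouring run
    repeat {
        r <- rle(state)
        if (length(r$lengths) <= 1L) break
        short <- which(r$lengths < minProbes)
        if (length(short) == 0L) break
        i <- short[1L]
        nbr <- c(if (i > 1L) i - 1L, if (i < length(r$lengths)) i + 1L)
        j <- nbr[which.max(r$lengths[nbr])]
        r$values[i] <- r$values[j]
        state <- inverse.rle(r)
    }
    r <- rle(state)
    idxEnd <- cumsum(r$lengths)
    idxStart <- c(1L, head(idxEnd, -1L) + 1L)
    segStart <- vapply(seq_along(idxStart), function(k) {
        if (k == 1L) track$start[1L]
        else (track$end[idxEnd[k - 1L]] + track$start[idxStart[k]]) %/% 2L
    }, numeric(1))
    segEnd <- vapply(seq_along(idxEnd), function(k) {
        if (k == length(idxEnd)) track$end[nrow(track)]
        else (track$end[idxEnd[k]] + track$start[idxStart[k + 1L]]) %/% 2L - 1L
    }, numeric(1))
    gr <- GenomicRanges::GRanges(chromName,
                                 IRanges::IRanges(segStart, segEnd))
    S4Vectors::mcols(gr)$state <- r$values
    S4Vectors::mcols(gr)$meanLog2 <- vapply(seq_along(idxStart),
        function(k) mean(track$log2[idxStart[k]:idxEnd[k]]), numeric(1))
    S4Vectors::mcols(gr)$nProbes <- r$lengths
    gr
}

#' Interpret the chrV L copy-number architecture
#'
#' Maps the non-neutral segments onto the assay feature map: the deletion
#' and duplication extents, the repetitive feature bounding the duplication
#' centromerically (\code{ura3-52} carries both the URA3 and Ty homology
#' tracts in this layout), and whether the hph-containing telomeric region
#' is retained.  A duplication whose telomeric boundary is not anchored in
#' the GCR breakpoint region is reported with a consistency warning.
#'
#' @param segments segment \linkS4class{GRanges} from
#'   \code{\link{segmentLog2Track}}.
#' @param reference an \linkS4class{AssayChromosome}.
#' @param boundaryTol tolerance in bp for matching a duplication boundary
#'   to a repeat feature (about the segmentation resolution).
#' @return a list (class \code{ChrVLArchitecture}) with deletionExtent,
#'   duplicationExtent (\linkS4class{GRanges} or NULL), boundaryFeature,
#'   telomericRetention and consistent.
#' @export
interpretChrVLArchitecture <- function(segments, reference,
                                       boundaryTol = 1500L) {
    st <- S4Vectors::mcols(segments)$state
    dup <- segments[st == "duplicated"]
    del <- segments[st == "deleted"]
    consistent <- TRUE

    bk <- .featSpan(reference, "GCR_breakpoint_region")
    boundaryFeature <- "none"
    dupExtent <- NULL
    if (length(dup) > 0L) {
        ## the assay duplication is the left-arm one (most telomeric)
        dupExtent <- dup[which.min(GenomicRanges::start(dup))]
        if (GenomicRanges::start(dupExtent) > bk[2L] + boundaryTol ||
            GenomicRanges::start(dupExtent) < bk[1L] - boundaryTol) {
            warning("duplication is not anchored in the GCR breakpoint ",
                    "region")
            consistent <- FALSE
        }
        cEnd <- GenomicRanges::end(dupExtent)
        for (f in c("ura3-52", "Ty")) {
            sp <- tryCatch(.featSpan(reference, f), error = function(e) NULL)
            if (!is.null(sp) && cEnd >= sp[1L] - boundaryTol &&
                cEnd <= sp[2L] + boundaryTol) {
                boundaryFeature <- f
                break
            }
        }
    }
    delExtent <- if (length(del) > 0L) del else NULL

    hphPos <- .featSpan(reference, "hph")[1L]
    telSeg <- segments[GenomicRanges::start(segments) <= hphPos &
                       GenomicRanges::end(segments) >= hphPos]
    telRetained <- length(telSeg) == 0L ||
        S4Vectors::mcols(telSeg)$state[1L] != "deleted"

    structure(list(deletionExtent = delExtent,
                   duplicationExtent = dupExtent,
                   nDuplications = length(dup),
                   boundaryFeature = boundaryFeature,
                   telomericRetention = telRetained,
                   consistent = consistent),
              class = "ChrVLArchitecture")
}

#' @export
print.ChrVLArchitecture <- function(x, ...) {
    fmt <- function(g) if (is.null(g)) "none" else
        paste(sprintf("%d-%d", GenomicRanges::start(g),
                      GenomicRanges::end(g)), collapse = ",")
    cat(sprintf(paste0("ChrVLArchitecture: deletion %s, duplication %s ",
                       "(boundary %s), hph side %s\n"),
                fmt(x$deletionExtent), fmt(x$duplicationExtent),
                x$boundaryFeature,
                if (x$telomericRetention) "retained" else "deleted"))
    invisible(x)
}

#' Analyse an MLPA run against a wild-type control
#'
#' Normalizes sample peak areas to the control using the median
#' control/sample ratio over the declared copy-neutral reference probes
#' (robust to a minority of changed probes), then calls amplified probes
#' (normalized ratio at or above \code{ampThreshold}, the midpoint of 1 and
#' 2 copies) and deleted probes (ratio at or below \code{delThreshold}).
#'
#' @param sample,control MLPA tables with columns probe, peak_area.
#' @param referenceProbes names of expected copy-neutral probes used for
#'   normalization.
#' @param ampThreshold normalized-ratio threshold for amplification.
#' @param delThreshold normalized-ratio threshold for deletion.
#' @return a list (class \code{MLPAResult}) with per-probe \code{ratio},
#'   \code{amplified}, \code{deleted} and \code{normalizationFactor}.
#' @export
analyzeMlpa <- function(sample, control, referenceProbes = NULL,
                        ampThreshold = 1.5, delThreshold = 0.3) {
    if (is.null(referenceProbes) && "reference" %in% names(sample))
        referenceProbes <- sample$probe[sample$reference]
    if (length(referenceProbes) == 0L)
        stop("at least one reference probe is required for normalization")
    if (!identical(sort(sample$probe), sort(control$probe)))
        stop("sample and control must share the probe set")
    control <- control[match(sample$probe, control$probe), , drop = FALSE]
    refIdx <- which(sample$probe %in% referenceProbes)
    if (any(sample$peak_area[refIdx] <= 0))
        stop("reference probes must have positive sample areas")
    normFactor <- median(control$peak_area[refIdx] /
                         sample$peak_area[refIdx])
    ratio <- (sample$peak_area / control$peak_area) * normFactor
    names(ratio) <- sample$probe
    structure(list(ratio = ratio,
                   amplified = sample$probe[ratio >= ampThreshold],
                   deleted = sample$probe[ratio <= delThreshold],
                   normalizationFactor = normFactor),
              class = "MLPAResult")
}

#' @export
print.MLPAResult <- function(x, ...) {
    cat(sprintf("MLPAResult: %d probes, amplified {%s}, deleted {%s}\n",
                length(x$ratio), paste(x$amplified, collapse = ","),
                paste(x$deleted, collapse = ",")))
    invisible(x)
}

#' Write a probe track as bedGraph (0-based half-open)
#'
#' @param track probe \code{data.frame} with start, end, log2 (1-based).
#' @param path output path.
#' @param chromName chromosome name.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path, chromName = "assay_chrV") {
    writeLines(sprintf("%s\t%d\t%d\t%.4f", chromName,
                       track$start - 1L, track$end, track$log2), path)
    invisible(path)
}

#' Read a bedGraph probe track (to 1-based inclusive coordinates)
#'
#' @param path bedGraph path.
#' @return probe \code{data.frame} with start, end, log2.
#' @export
readBedGraph <- function(path) {
    df <- utils::read.table(path, sep = "\t",
                            col.names = c("chrom", "start", "end", "log2"))
    data.frame(start = df$start + 1L, end = df$end, log2 = df$log2)
}
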