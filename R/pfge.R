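#' @include rearrangements.R
NULL

#' In-silico AscI digestion with probe hybridization (PFGE emulation)
#'
#' Cuts the genome at every occurrence of the enzyme motif (AscI,
#' \code{GGCGCGCC}, cutting after GG) and reports, per fragment, which
#' probe tracts hybridize.  The default probes are the \code{hph} and
#' \code{MCM3} homology tracts extracted from the reference, so on the
#' unrearranged assay chromosome the hph probe lights up the left
#' telomeric and internal fragments (the internal AscI fragment carries a
#' second hph-homologous tract) and the MCM3 probe only the internal
#' fragment.  The chromosome size class relative to the unrearranged
#' reference uses a gel-resolution tolerance band.
#'
#' @param genome a \linkS4class{DNAString},
#'   \linkS4class{RearrangedIsolate} or \linkS4class{AssayChromosome}.
#' @param reference the unrearranged \linkS4class{AssayChromosome}.
#' @param motif enzyme recognition motif.
#' @param probes named character vector of probe sequences; defaults to
#'   cores of the reference hph and MCM3 tracts.
#' @param tolerance size-class tolerance band (fraction of the reference
#'   length counted as "similar to wild type").
#' @return a list (class \code{PFGEDigest}) with \code{fragments} (a
#'   \code{data.frame} of start, end, length and per-probe hybridization),
#'   \code{sizeClass} and \code{totalLength}.
#' @export
insilicoPfge <- function(genome, reference, motif = "GGCGCGCC",
                         probes = NULL, tolerance = 0.02) {
    if (is(genome, "RearrangedIsolate")) {
        if (missing(reference)) reference <- refChromosome(genome)
        genome <- productSeq(genome)
    }
    if (is(genome, "AssayChromosome")) genome <- chromSequence(genome)
    stopifnot(is(genome, "DNAString"), is(reference, "AssayChromosome"))
    if (is.null(probes)) {
        hph <- featureSeq(reference, "hph")
        probes <- c(hph = substr(hph, 200L, 350L),
                    MCM3 = substr(featureSeq(reference, "MCM3"),
                                  50L, 200L))
    }
    L <- length(genome)
    cutSites <- Biostrings::start(Biostrings::matchPattern(
        Biostrings::DNAString(motif), genome))
    if (length(cutSites) == 0L)
        warning("no cut sites; reporting a single fragment")
    cutAt <- cutSites + 2L                       # AscI cuts GG^CGCGCC
    starts <- c(1L, cutAt)
    ends <- c(cutAt - 1L, L)
    frag <- data.frame(start = starts, end = ends,
                       length = ends - starts + 1L)
    for (pn in names(probes)) {
        pat <- Biostrings::DNAString(probes[[pn]])
        frag[[pn]] <- vapply(seq_len(nrow(frag)), function(i) {
            sub <- Biostrings::subseq(genome, frag$start[i], frag$end[i])
            length(Biostrings::matchPattern(pat, sub)) > 0L ||
                length(Biostrings::matchPattern(
                    Biostrings::reverseComplement(pat), sub)) > 0L
        }, logical(1))
    }
    structure(list(fragments = frag,
                   sizeClass = {
                       sc <- sizeClassOf(L, chromLength(reference),
                                         tolerance)
                       c(wild_type_like = "similar", larger = "larger",
                         smaller = "smaller")[[sc]]
                   },
                   totalLength = L),
              class = "PFGEDigest")
}

#' @export
print.PFGEDigest <- function(x, ...) {
    cat(sprintf("PFGEDigest: %d fragments, total %d bp, size class %s\n",
                nrow(x$fragments), x$totalLength, x$sizeClass))
    print(x$fragments, row.names = FALSE)
    invisible(x)
}

#' Test hph marker presence in a genome sequence
#'
#' Synthetic-mode proxy for growth on hygromycin: the genome retains hph
#' iff it contains the telomeric hph probe tract (the internal
#' hph-homologous tract is a subsequence of it, so a genome retaining only
#' the internal tract still scores positive for hph homology — matching
#' Southern hybridization, while marker function is scored on the
#' telomeric full-length tract).
#'
#' @param genome a \linkS4class{DNAString}, isolate or chromosome.
#' @param reference the \linkS4class{AssayChromosome}.
#' @return logical: is the full hph tract present?
#' @export
hphPresent <- function(genome, reference) {
    if (is(genome, "RearrangedIsolate")) {
        if (missing(reference)) reference <- refChromosome(genome)
        genome <- productSeq(genome)
    }
    if (is(genome, "AssayChromosome")) genome <- chromSequence(genome)
    pat <- Biostrings::DNAString(featureSeq(reference, "hph"))
    length(Biostrings::matchPattern(pat, genome)) > 0L
}
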