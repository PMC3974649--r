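#' @include AllClasses.R AllGenerics.R utils.R
NULL

.ASC_MOTIF <- "GGCGCGCC"

## Fixed marker tract sequences, generated once per session from dedicated
## seeds so that the same recognizable hph/URA3/Ty sequences appear in every
## assay chromosome regardless of the layout seed.  Scrubbed of AscI motifs.
.tractCache <- new.env(parent = emptyenv())

markerTract <- function(which = c("hph", "URA3_core", "Ty", "CAN1core")) {
    which <- match.arg(which)
    if (!is.null(.tractCache[[which]])) return(.tractCache[[which]])
    spec <- list(hph = c(seed = 101L, len = 600L),
                 URA3_core = c(seed = 102L, len = 300L),
                 Ty = c(seed = 103L, len = 500L),
                 CAN1core = c(seed = 104L, len = 800L))[[which]]
    tract <- withSeed(spec[["seed"]], randDna(spec[["len"]]))
    tract <- scrubMotif(tract, .ASC_MOTIF)
    .tractCache[[which]] <- tract
    tract
}

## Layout fractions (of chromosome length); tract widths are fixed in bp so
## that scaled-down test chromosomes keep realistic marker sizes.
.LAYOUT_FRACS <- c(hph = 0.018, AscI1 = 0.032, cassette = 0.044,
                   bkptPad = 200, PCM1 = 0.13, VMA8 = 0.155, BUD16 = 0.17,
                   GEA2 = 0.185, ura3_52 = 0.20, CEN5 = 0.26,
                   hph_internal = 0.35, MCM3 = 0.42, AscI2 = 0.90)

#' Build the model assay chromosome
#'
#' Constructs a synthetic chromosome V for the marker-loss GCR assays.  The
#' sequence is pseudo-random at a fixed seed except for recognizable feature
#' tracts: the telomeric TG1-3 seeds, the \code{hph} marker (plus a second
#' hph-homologous tract internal to the two AscI sites, so the internal AscI
#' fragment carries hph homology), the \code{CAN1/URA3} cassette, a
#' Ty-consensus tract and a \code{URA3}-homologous core stored in inverted
#' orientation at \code{ura3-52} (the homology that resolves inverted
#' duplications), and the AscI recognition motif \code{GGCGCGCC} at exactly
#' the annotated sites (chance occurrences are scrubbed).
#'
#' @param length chromosome length in bp (default 580000, roughly chrV;
#'   minimum 50000 for scaled-down layouts).
#' @param assay assay variant; \code{"ugcr"} (default) places the cassette at
#'   the yel068c-like position, \code{"dgcr"} slightly more telomeric.
#' @param seed RNG seed for the pseudo-random backbone.
#' @param name chromosome name.
#' @return an \linkS4class{AssayChromosome}.
#' @examples
#' chrom <- buildAssayChromosome(length = 50000, seed = 1)
#' chromLength(chrom)
#' featureRange(chrom, "hph")
#' @export
buildAssayChromosome <- function(length = 580000L,
                                 assay = c("ugcr", "dgcr"),
                                 seed = 1L, name = "assay_chrV") {
    assay <- match.arg(assay)
    L <- as.integer(length)
    if (is.na(L) || L < 50000L)
        stop("chromosome length must be at least 50,000 bp")
    fr <- .LAYOUT_FRACS
    if (assay == "dgcr") fr[["cassette"]] <- 0.036
    if (fr[["cassette"]] <= fr[["hph"]])
        stop("layout places the cassette telomeric to hph; the assay ",
             "requires TEL_L < hph < CAN1/URA3 cassette")

    hph <- markerTract("hph")
    ura3core <- markerTract("URA3_core")
    ty <- markerTract("Ty")
    can1 <- markerTract("CAN1core")

    seq <- withSeed(seed, {
        backbone <- randDna(L)

        telL <- tgTract(120L, minWidth = 250L)
        telR <- revcompStr(tgTract(120L, minWidth = 250L))

        at <- function(f) as.integer(round(fr[[f]] * L))
        pos <- list()
        place <- function(s, start, tract, nm) {
            pos[[nm]] <<- c(start, start + nchar(tract) - 1L)
            strAssign(s, start, tract)
        }
        s <- backbone
        s <- place(s, 1L, telL, "TEL_L")
        s <- place(s, at("hph"), hph, "hph")
        s <- place(s, at("AscI1"), .ASC_MOTIF, "AscI1")
        ## cassette: URA3 telomeric of CAN1, so the URA3/ura3-52 capture of
        ## the telomeric fragment loses CAN1 (required by the selection)
        ura3Start <- at("cassette")
        ura3Tract <- paste0(randDna(100L), ura3core, randDna(100L))
        s <- place(s, ura3Start, ura3Tract, "URA3")
        s <- place(s, ura3Start + nchar(ura3Tract) + 100L, can1, "CAN1")
        s <- place(s, at("PCM1"), randDna(600L), "PCM1")
        s <- place(s, at("VMA8"), randDna(300L), "VMA8")
        s <- place(s, at("BUD16"), randDna(300L), "BUD16")
        s <- place(s, at("GEA2"), randDna(300L), "GEA2")
        ## ura3-52: URA3 homology core and a Ty consensus tract, both stored
        ## in inverted orientation so that the fold-back duplication presents
        ## them co-oriented with the cassette URA3 / donor Ty.
        ura52Tract <- paste0(revcompStr(ura3core), revcompStr(ty))
        s <- place(s, at("ura3_52"), ura52Tract, "ura3-52")
        s <- place(s, at("CEN5"), randDna(120L), "CEN5")
        s <- place(s, at("hph_internal"), substr(hph, 151L, 450L),
                   "hph_internal")
        s <- place(s, at("MCM3"), randDna(400L), "MCM3")
        s <- place(s, at("AscI2"), .ASC_MOTIF, "AscI2")
        s <- place(s, L - nchar(telR) + 1L, telR, "TEL_R")
        s <- scrubMotif(s, .ASC_MOTIF,
                        allowedStarts = c(pos[["AscI1"]][1L],
                                          pos[["AscI2"]][1L]))
        attr(s, "pos") <- pos
        s
    })
    pos <- attr(seq, "pos")
    attr(seq, "pos") <- NULL

    cassetteEnd <- max(pos[["URA3"]][2L], pos[["CAN1"]][2L])
    bkpt <- c(cassetteEnd + as.integer(fr[["bkptPad"]]),
              pos[["PCM1"]][1L] - as.integer(fr[["bkptPad"]]))
    pos[["GCR_breakpoint_region"]] <- bkpt

    nm <- names(pos)
    nm[nm == "AscI1"] <- "AscI"
    nm[nm == "AscI2"] <- "AscI"
    gr <- GenomicRanges::GRanges(
        seqnames = name,
        ranges = IRanges::IRanges(start = vapply(pos, `[`, integer(1), 1L),
                                  end = vapply(pos, `[`, integer(1), 2L)),
        strand = "*",
        seqlengths = stats::setNames(L, name))
    names(gr) <- nm
    gr <- sort(gr)

    new("AssayChromosome", chromName = name,
        sequence = Biostrings::DNAString(seq), features = gr)
}

#' @rdname accessors
#' @export
setMethod("chromName", "AssayChromosome", function(x) x@chromName)
#' @rdname accessors
#' @export
setMethod("chromSequence", "AssayChromosome", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("chromFeatures", "AssayChromosome", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("chromLength", "AssayChromosome", function(x) length(x@sequence))

#' @rdname featureRange
#' @export
setMethod("featureRange", "AssayChromosome", function(x, name) {
    hit <- x@features[names(x@features) == name]
    if (length(hit) == 0L) stop("no feature named '", name, "'")
    hit
})

#' @rdname featureSeq
#' @export
setMethod("featureSeq", "AssayChromosome", function(x, name) {
    r <- featureRange(x, name)[1L]
    as.character(Biostrings::subseq(x@sequence,
                                    GenomicRanges::start(r),
                                    GenomicRanges::end(r)))
})

setMethod("show", "AssayChromosome", function(object) {
    cat(sprintf("AssayChromosome '%s': %d bp, %d features\n",
                object@chromName, chromLength(object),
                length(object@features)))
    cat("  features:", paste(unique(names(object@features)), collapse = ", "),
        "\n")
})

#' @rdname accessors
#' @export
setMethod("eventClass", "RearrangementTruth", function(x) x@eventClass)
#' @rdname accessors
#' @export
setMethod("eventClass", "RearrangedIsolate", function(x) x@truth@eventClass)
#' @rdname accessors
#' @export
setMethod("truth", "RearrangedIsolate", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("productSeq", "RearrangedIsolate", function(x) x@product)
#' @rdname accessors
#' @export
setMethod("refChromosome", "RearrangedIsolate", function(x) x@reference)

setMethod("show", "RearrangementTruth", function(object) {
    cat(sprintf("RearrangementTruth: %s (hph %s, size %s)\n",
                object@eventClass,
                if (object@expectHph) "retained" else "lost",
                object@expectSizeClass))
    cat("  coords:", paste(names(object@coords), object@coords,
                           sep = "=", collapse = " "), "\n")
})

setMethod("show", "RearrangedIsolate", function(object) {
    cat(sprintf("RearrangedIsolate: %s product of %d bp (reference %d bp)\n",
                object@truth@eventClass, length(object@product),
                chromLength(object@reference)))
})
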