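#' @include classifier.R stats.R
NULL

#' Draw a truth-labelled rearranged isolate of a given class
#'
#' Event parameters are drawn from the ranges the assay products occupy:
#' interstitial deletions span the CAN1/URA3 cassette with 0-5 bp junction
#' microhomology; fold-back inverted duplications use hairpin loops of
#' 25-44 nt and priming homologies of 3-9 bp resolved via URA3/ura3-52;
#' de novo telomeres and translocations break inside the GCR breakpoint
#' region.
#'
#' @param chrom the \linkS4class{AssayChromosome}.
#' @param class event class.
#' @param seed RNG seed for the parameter draw.
#' @return a \linkS4class{RearrangedIsolate}.
#' @export
drawIsolate <- function(chrom,
                        class = c("interstitial_deletion",
                                  "inverted_duplication",
                                  "de_novo_telomere", "translocation"),
                        seed = 1L, resolution = "URA3/ura3-52") {
    class <- match.arg(class)
    L <- chromLength(chrom)
    bk <- .featSpan(chrom, "GCR_breakpoint_region")
    cass <- range(c(.featSpan(chrom, "CAN1"), .featSpan(chrom, "URA3")))
    withSeed(seed, {
        switch(class,
        interstitial_deletion = {
            start <- cass[1L] - sample(100:400, 1L)
            end <- sample(seq.int(bk[1L] + 500L, bk[2L] - 200L), 1L)
            applyInterstitialDeletion(chrom, start, end,
                                      microhomology = sample(0:5, 1L))
        },
        inverted_duplication = {
            dsb <- sample(seq.int(bk[1L] + 100L, bk[1L] + 1000L), 1L)
            applyInvertedDuplication(chrom, dsb,
                                     foldback = dsb + sample(50:300, 1L),
                                     loop = sample(25:44, 1L),
                                     primingHomology = sample(3:9, 1L),
                                     resolution = resolution)
        },
        de_novo_telomere = {
            pos <- sample(seq.int(bk[1L] + 100L, bk[2L] - 100L), 1L)
            applyDeNovoTelomere(chrom, pos, seedRepeats = 25L)
        },
        translocation = {
            pos <- sample(seq.int(bk[1L] + 100L, bk[2L] - 100L), 1L)
            donorStart <- as.integer(round(0.60 * L)) + sample(0:2000, 1L)
            donor <- substr(.refStr(chrom), donorStart, donorStart + 2999L)
            applyTranslocation(chrom, pos, donor,
                               donorLabel = "right-arm donor",
                               donorCoords = c(donorStart,
                                               donorStart + 2999L))
        })
    })
}

#' Analyse one isolate end-to-end
#'
#' Simulate the paired-end library from the rearranged genome, map it back
#' to the assay reference, deduplicate, estimate insert statistics, call
#' and annotate junctions (with one-sided junction-read recruitment at a
#' copy-number terminal-deletion boundary when clustering finds nothing —
#' de novo telomere junctions have no junction-defining pairs because one
#' side is unmappable), interpret aCGH copy number, digest in silico, and
#' classify.
#'
#' @param isolate a \linkS4class{RearrangedIsolate}.
#' @param model a \linkS4class{LibraryModel} (its seed is used).
#' @param id isolate id.
#' @param acghNoiseSd,probeSpacing aCGH simulation parameters.
#' @param minSupport,minSupportFoldback,alpha caller thresholds.
#' @param samPath optional path: when given the mapped pairs are written
#'   as SAM and re-loaded through the SAM reader (slower; exercises the
#'   file interface).
#' @param seed seed for the array simulators.
#' @return a list with pairs statistics, calls, annotations, architecture,
#'   digest, mlpa, and the \linkS4class{GCRClassification}.
#' @export
runIsolate <- function(isolate, model = libraryModel(), id = "isolate",
                       acghNoiseSd = 0.1, probeSpacing = NULL,
                       minSupport = 3L, minSupportFoldback = 2L,
                       alpha = 0.01, samPath = NULL, seed = 1L) {
    stopifnot(is(isolate, "RearrangedIsolate"))
    reference <- refChromosome(isolate)
    ## default probe density scales with the chromosome so scaled-down test
    ## layouts keep enough probes per marker-sized interval
    if (is.null(probeSpacing))
        probeSpacing <- max(50L, min(500L,
            as.integer(round(chromLength(reference) / 200))))
    pairs <- simulateReadPairs(isolate, model)
    mapped <- mapPairsToReference(pairs, reference)
    if (!is.null(samPath)) {
        writeSam(mapped, reference, samPath)
        mapped <- loadMappedPairs(samPath)
    }
    dd <- deduplicatePairs(mapped)
    stats <- estimateInsertStats(dd)
    calls <- clusterJunctionPairs(dd, stats, minSupport = minSupport,
                                  minSupportFoldback = minSupportFoldback,
                                  alpha = alpha,
                                  targetLength = chromLength(reference))
    sig <- Filter(isSignificant, calls)

    annotations <- list()
    for (call in sig) {
        reads <- recruitJunctionReads(call, dd, stats)
        if (length(reads) == 0L) next
        cons <- assembleJunctionConsensus(reads)
        if (length(cons@consensus) < 40L) next
        annotations[[length(annotations) + 1L]] <-
            c(annotateJunction(cons, reference), list(consensus = cons))
    }

    track <- simulateAcgh(isolate, probeSpacing = probeSpacing,
                          noiseSd = acghNoiseSd,
                          seed = fanSeed(seed, 11L))
    segments <- segmentLog2Track(track, chromName = chromName(reference))
    arch <- interpretChrVLArchitecture(segments, reference,
                                       boundaryTol = 3L * probeSpacing)

    ## one-sided rescue at a terminal-deletion boundary (telomere additions
    ## and translocations whose junction-defining pairs were missed)
    if (length(annotations) == 0L && !is.null(arch$deletionExtent)) {
        term <- arch$deletionExtent[
            GenomicRanges::start(arch$deletionExtent) <= 2L * probeSpacing]
        if (length(term) > 0L) {
            bnd <- GenomicRanges::end(term)[1L]
            anchor <- GenomicRanges::GRanges(chromName(reference),
                IRanges::IRanges(bnd, bnd + 1L), strand = "*")
            reads <- recruitJunctionReads(NULL, dd, stats, anchor = anchor)
            if (length(reads) > 0L) {
                cons <- assembleJunctionConsensus(reads)
                if (length(cons@consensus) >= 40L)
                    annotations[[1L]] <-
                        c(annotateJunction(cons, reference),
                          list(consensus = cons))
            }
        }
    }

    control <- simulateMlpa(NULL, reference, noiseCv = 0.05,
                            seed = fanSeed(seed, 13L))
    sample <- simulateMlpa(isolate, reference, noiseCv = 0.05,
                           seed = fanSeed(seed, 17L))
    mlpa <- analyzeMlpa(sample, control)

    digest <- insilicoPfge(isolate)
    hph <- hphPresent(isolate)
    cls <- classifyGcr(annotations, arch, digest, hph, isolate = id)
    list(id = id, insertStats = stats, calls = calls,
         significantCalls = sig, annotations = annotations,
         track = track, segments = segments, architecture = arch,
         mlpa = mlpa, digest = digest, hph = hph, classification = cls,
         truth = truth(isolate))
}

#' Cohort configuration
#'
#' @param nPerClass isolates per event class.
#' @param classes event classes to include.
#' @param chromLength assay chromosome length in bp.
#' @param coverage,insertMean,insertSd,readLength,dupFraction library
#'   parameters.
#' @param acghNoiseSd aCGH noise sd (log2 units).
#' @param seed global seed; fanned out to per-stage, per-isolate seeds.
#' @param events optional explicit event mix: a \code{data.frame} with
#'   columns \code{class} and (optionally) \code{resolution}, one row per
#'   isolate; overrides \code{nPerClass}/\code{classes}.  May have zero
#'   rows for an empty cohort.
#' @return a list of class \code{CohortConfig}.
#' @export
cohortConfig <- function(nPerClass = 5L,
                         classes = c("interstitial_deletion",
                                     "inverted_duplication",
                                     "de_novo_telomere", "translocation"),
                         chromLength = 50000L, coverage = 50,
                         insertMean = 600, insertSd = 60,
                         readLength = 100L, dupFraction = 0,
                         acghNoiseSd = 0.1, seed = 1L, events = NULL) {
    structure(list(nPerClass = as.integer(nPerClass), classes = classes,
                   chromLength = as.integer(chromLength),
                   coverage = coverage, insertMean = insertMean,
                   insertSd = insertSd, readLength = as.integer(readLength),
                   dupFraction = dupFraction, acghNoiseSd = acghNoiseSd,
                   seed = as.integer(seed), events = events),
              class = "CohortConfig")
}

#' Run a synthetic cohort end-to-end
#'
#' Builds the assay chromosome, draws \code{nPerClass} truth-labelled
#' isolates per event class, analyses each end-to-end and summarises:
#' per-isolate classifications against truth, the duplication-by-hph
#' two-way table, and hph retention.  Deterministic for a fixed config.
#'
#' @param config a \code{CohortConfig}.
#' @param genotype genotype label for the retention table.
#' @return a list with \code{results} (per isolate), \code{summary}
#'   (one row per isolate: truth and called class, hph truth/called),
#'   \code{twoWay} and \code{retention}.
#' @export
runCohort <- function(config = cohortConfig(), genotype = "synthetic") {
    chrom <- buildAssayChromosome(length = config$chromLength,
                                  seed = fanSeed(config$seed, 1L))
    if (!is.null(config$events)) {
        specs <- config$events
        specs$rep <- seq_len(nrow(specs))
    } else {
        specs <- expand.grid(rep = seq_len(config$nPerClass),
                             class = config$classes,
                             stringsAsFactors = FALSE)
    }
    if (is.null(specs$resolution))
        specs$resolution <- rep("URA3/ura3-52", nrow(specs))
    if (nrow(specs) == 0L)
        return(list(results = list(),
                    summary = data.frame(id = character(0),
                                         truthClass = character(0),
                                         calledClass = character(0),
                                         truthHph = logical(0),
                                         calledHph = logical(0),
                                         nSignificantCalls = integer(0)),
                    twoWay = duplicationByHphTable(list()),
                    retention = data.frame(genotype = character(0),
                                           retaining = integer(0),
                                           total = integer(0),
                                           percent = numeric(0)),
                    chrom = chrom))
    results <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
        isoSeed <- fanSeed(config$seed, 100L + i)
        iso <- drawIsolate(chrom, specs$class[i], seed = isoSeed,
                           resolution = specs$resolution[i])
        model <- libraryModel(insertMean = config$insertMean,
                              insertSd = config$insertSd,
                              readLength = config$readLength,
                              coverage = config$coverage,
                              dupFraction = config$dupFraction,
                              seed = fanSeed(isoSeed, 2L))
        results[[i]] <- runIsolate(iso, model,
                                   id = sprintf("%s_%02d", specs$class[i],
                                                specs$rep[i]),
                                   acghNoiseSd = config$acghNoiseSd,
                                   seed = fanSeed(isoSeed, 3L))
    }
    summary <- do.call(rbind, lapply(results, function(r) {
        data.frame(id = r$id,
                   truthClass = r$truth@eventClass,
                   calledClass = r$classification@gcrClass,
                   truthHph = r$truth@expectHph,
                   calledHph = r$classification@hphRetained,
                   nSignificantCalls = length(r$significantCalls))
    }))
    retention <- tabulateRetention(
        data.frame(genotype = genotype,
                   retained = summary$calledHph))
    list(results = results, summary = summary,
         twoWay = duplicationByHphTable(
             lapply(results, `[[`, "classification")),
         retention = retention,
         chrom = chrom)
}
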