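#' @include rearrangements.R
NULL

#' Simulate an aCGH log2-ratio probe track
#'
#' One probe per reference window of \code{probeSpacing} bp.  The probe
#' value is \code{log2} of the copy number of its window in the rearranged
#' genome (haploid semantics: duplication is +1, neutral 0) plus Gaussian
#' noise; windows with copy number 0 are reported at a configurable floor.
#' Windows covering the \code{hph} and \code{CAN1} marker insertions are
#' omitted (these non-native sequences are not probed by the array), as is
#' the internal hph-homologous tract.
#'
#' @param isolate a \linkS4class{RearrangedIsolate} (copy number is taken
#'   from its truth record by interval accounting), or a
#'   \linkS4class{RearrangementTruth} with \code{reference} supplied.
#' @param reference the \linkS4class{AssayChromosome}; defaults to the
#'   isolate's reference.
#' @param probeSpacing probe spacing in bp (>= 50).
#' @param noiseSd Gaussian noise sd in log2 units.
#' @param seed RNG seed.
#' @param floor reported log2 value for copy-number-0 windows.
#' @return a \code{data.frame} with columns start, end, log2 (1-based
#'   inclusive probe windows, coordinate-sorted).
#' @export
simulateAcgh <- function(isolate, reference = NULL, probeSpacing = 500L,
                         noiseSd = 0.1, seed = 1L, floor = -4) {
    if (is(isolate, "RearrangedIsolate")) {
        reference <- reference %||% refChromosome(isolate)
        tr <- truth(isolate)
    } else {
        tr <- isolate
        if (is.null(reference)) stop("reference required")
    }
    probeSpacing <- as.integer(probeSpacing)
    if (probeSpacing < 50L) stop("probe spacing must be at least 50 bp")
    L <- chromLength(reference)
    cn <- if (is.null(tr)) rep.int(1L, L) else truthCopyNumber(tr, L)

    starts <- seq.int(1L, L - probeSpacing + 1L, by = probeSpacing)
    ends <- starts + probeSpacing - 1L
    mids <- (starts + ends) %/% 2L

    omit <- rep(FALSE, length(starts))
    for (f in c("hph", "CAN1", "hph_internal")) {
        sp <- .featSpan(reference, f)
        omit <- omit | (starts <= sp[2L] & ends >= sp[1L])
    }
    starts <- starts[!omit]; ends <- ends[!omit]; mids <- mids[!omit]

    vals <- withSeed(seed, {
        v <- ifelse(cn[mids] == 0L, floor, log2(cn[mids]))
        v + if (noiseSd > 0) rnorm(length(v), 0, noiseSd) else 0
    })
    data.frame(start = starts, end = ends, log2 = vals)
}

#' Simulate an unrearranged (copy-neutral) aCGH track
#'
#' @param reference an \linkS4class{AssayChromosome}.
#' @inheritParams simulateAcgh
#' @return a probe track \code{data.frame} as \code{\link{simulateAcgh}}.
#' @export
simulateNullAcgh <- function(reference, probeSpacing = 500L, noiseSd = 0.1,
                             seed = 1L) {
    simulateAcgh(NULL, reference = reference, probeSpacing = probeSpacing,
                 noiseSd = noiseSd, seed = seed)
}

#' Default MLPA probe set for the chrV L assay chromosome
#'
#' Probes target single-copy loci along the assay chromosome, emulating
#' the documented design rule that amplification-product lengths differ by
#' 6 bp and the gene targets of the chrV L probe set (including PCM1,
#' VMA8, BUD16 and GEA2 inside the recurrent duplication interval).  The
#' reference (expected copy-neutral) probes are the centromere-proximal
#' and right-arm probes.
#'
#' @param reference an \linkS4class{AssayChromosome}.
#' @return a \code{data.frame} with columns probe, target_start,
#'   product_length, reference (logical: usable for normalization).
#' @export
defaultMlpaProbes <- function(reference) {
    L <- chromLength(reference)
    at <- function(f) .featSpan(reference, f)[1L] + 50L
    probes <- data.frame(
        probe = c("YEL068C", "PCM1", "VMA8", "BUD16", "GEA2",
                  "CEN5prox", "MCM3", "RARM1", "RARM2"),
        target_start = c(.featSpan(reference, "CAN1")[1L] + 50L,
                         at("PCM1"), at("VMA8"), at("BUD16"), at("GEA2"),
                         at("CEN5") - 2000L, at("MCM3"),
                         as.integer(round(0.55 * L)),
                         as.integer(round(0.75 * L))),
        reference = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                      TRUE, TRUE, TRUE, TRUE))
    probes$product_length <- 100L + 6L * (seq_len(nrow(probes)) - 1L)
    probes
}

#' Simulate an MLPA peak-area table
#'
#' Peak area is proportional to the copy number of the probe target in the
#' rearranged genome, with multiplicative Gaussian noise of relative
#' magnitude \code{noiseCv}; probes whose target is absent get area 0 (up
#' to noise on a zero signal, i.e. exactly 0).
#'
#' @param isolate a \linkS4class{RearrangedIsolate}, a
#'   \linkS4class{RearrangementTruth}, or \code{NULL} for an unrearranged
#'   control.
#' @param reference the \linkS4class{AssayChromosome}.
#' @param probes probe table from \code{\link{defaultMlpaProbes}}.
#' @param noiseCv coefficient of variation of the peak areas.
#' @param seed RNG seed.
#' @param baseline single-copy peak area.
#' @return the probe table with a \code{peak_area} column.
#' @export
simulateMlpa <- function(isolate, reference = NULL,
                         probes = NULL, noiseCv = 0.05, seed = 1L,
                         baseline = 1000) {
    tr <- NULL
    if (is(isolate, "RearrangedIsolate")) {
        reference <- reference %||% refChromosome(isolate)
        tr <- truth(isolate)
    } else if (is(isolate, "RearrangementTruth")) {
        tr <- isolate
    }
    if (is.null(reference)) stop("reference required")
    if (is.null(probes)) probes <- defaultMlpaProbes(reference)
    dl <- diff(probes$product_length)
    if (any(dl != 6L))
        stop("probe product lengths must increase in 6 bp steps")
    L <- chromLength(reference)
    cn <- if (is.null(tr)) rep.int(1L, L) else truthCopyNumber(tr, L)
    probes$peak_area <- withSeed(seed, {
        noise <- if (noiseCv > 0) rnorm(nrow(probes), 0, noiseCv) else 0
        baseline * cn[probes$target_start] * (1 + noise)
    })
    probes
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Mutations arise during exponential growth at \code{rate} events per cell
#' division; the number of mutations per culture is Poisson with mean
#' \code{rate * finalCells}, and each mutant clone expands deterministically
#' so its final size is \code{floor(1/u)} for a uniform draw u (capped at
#' the culture size), giving the characteristic heavy-tailed mutant-count
#' distribution.
#'
#' @param rate mutation rate per cell division (0 to 1e-4).
#' @param nCultures number of parallel cultures.
#' @param finalCells final cells per culture (>= 1e4).
#' @param seed RNG seed.
#' @return a list (class \code{FluctuationExperiment}) with \code{counts},
#'   \code{cellsPerCulture} and \code{trueRate}.
#' @export
simulateFluctuationAssay <- function(rate, nCultures = 24L,
                                     finalCells = 1e8, seed = 1L) {
    if (rate < 0 || rate > 1e-4) stop("rate must be in [0, 1e-4]")
    if (finalCells < 1e4) stop("finalCells must be at least 1e4")
    nCultures <- as.integer(nCultures)
    if (nCultures < 1L) stop("at least one culture is required")
    counts <- withSeed(seed, {
        m <- rate * finalCells
        vapply(seq_len(nCultures), function(i) {
            k <- rpois(1L, m)
            if (k == 0L) return(0)
            sum(pmin(floor(1 / runif(k)), finalCells))
        }, numeric(1))
    })
    structure(list(counts = counts, cellsPerCulture = finalCells,
                   trueRate = rate),
              class = "FluctuationExperiment")
}

#' @export
print.FluctuationExperiment <- function(x, ...) {
    cat(sprintf(
        "FluctuationExperiment: %d cultures of %.3g cells, median count %g\n",
        length(x$counts), x$cellsPerCulture, median(x$counts)))
    invisible(x)
}
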