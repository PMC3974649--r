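test_that("segmentation of clean tracks recovers states and boundaries", {
    ## flat zero track -> one neutral segment
    flat <- data.frame(start = seq(1, 49501, by = 500),
                       end = seq(500, 50000, by = 500), log2 = 0)
    seg <- segmentLog2Track(flat)
    expect_identical(length(seg), 1L)
    expect_identical(S4Vectors::mcols(seg)$state, "neutral")
    ## noise-free +1 step over [30k, 110k) at 500 bp spacing
    tr <- data.frame(start = seq(1, 199501, by = 500),
                     end = seq(500, 200000, by = 500))
    tr$log2 <- ifelse(tr$start >= 30001 & tr$end <= 110000, 1, 0)
    seg2 <- segmentLog2Track(tr)
    dup <- seg2[S4Vectors::mcols(seg2)$state == "duplicated"]
    expect_identical(length(dup), 1L)
    expect_lte(abs(GenomicRanges::start(dup) - 30001), 500)
    expect_lte(abs(GenomicRanges::end(dup) - 110000), 500)
    ## deleted intervals at the floor
    tr$log2[tr$start >= 150001 & tr$end <= 160000] <- -4
    seg3 <- segmentLog2Track(tr)
    expect_true("deleted" %in% S4Vectors::mcols(seg3)$state)
    ## unsorted input rejected
    expect_error(segmentLog2Track(tr[rev(seq_len(nrow(tr))), ]), "sorted")
})

test_that("segmentation boundaries are stable under probe noise", {
    tr0 <- data.frame(start = seq(1, 199501, by = 500),
                      end = seq(500, 200000, by = 500))
    mu <- ifelse(tr0$start >= 30001 & tr0$end <= 110000, 1, 0)
    ok <- 0L
    for (s in 1:100) {
        set.seed(s)
        tr <- tr0
        tr$log2 <- mu + rnorm(nrow(tr0), 0, 0.2)
        seg <- segmentLog2Track(tr)
        dup <- seg[S4Vectors::mcols(seg)$state == "duplicated"]
        if (length(dup) == 1L &&
            abs(GenomicRanges::start(dup) - 30001) <= 1000 &&
            abs(GenomicRanges::end(dup) - 110000) <= 1000)
            ok <- ok + 1L
    }
    expect_gte(ok, 95L)
})

test_that("segmentation is idempotent and order-invariant after sorting", {
    set.seed(9)
    tr <- data.frame(start = seq(1, 49501, by = 500),
                     end = seq(500, 50000, by = 500))
    tr$log2 <- rnorm(nrow(tr), 0, 0.15)
    seg1 <- segmentLog2Track(tr)
    perm <- tr[sample(nrow(tr)), ]
    perm <- perm[order(perm$start), ]
    expect_identical(segmentLog2Track(perm), seg1)
})

test_that("aCGH simulation reports exact log2 states without noise", {
    chrom <- fxChrom()
    ## unrearranged, noise 0 -> all probes exactly 0
    null <- simulateAcgh(NULL, chrom, probeSpacing = 250, noiseSd = 0)
    expect_true(all(null$log2 == 0))
    ## probes are omitted over the hph/CAN1 marker insertions
    hph <- featureRange(chrom, "hph")
    expect_false(any(null$start <= GenomicRanges::end(hph) &
                     null$end >= GenomicRanges::start(hph)))
    ## duplication at exactly +1, deletion at the floor
    iso <- applyInvertedDuplication(chrom, 4000, 4200, 30, 5)
    tr <- simulateAcgh(iso, probeSpacing = 250, noiseSd = 0)
    co <- truth(iso)@coords
    inDup <- tr$start >= co[["dupStart"]] & tr$end <= co[["dupEnd"]]
    expect_true(all(tr$log2[inDup] == 1))
    inDel <- tr$start >= co[["delStart"]] & tr$end <= co[["delEnd"]]
    expect_true(all(tr$log2[inDel] == -4))
    expect_error(simulateAcgh(iso, probeSpacing = 20), "50")
    ## bedGraph round trip
    p <- tempfile(fileext = ".bedGraph")
    writeBedGraph(tr, p)
    back <- readBedGraph(p)
    expect_equal(back$log2, tr$log2, tolerance = 1e-4)
    expect_identical(back$start, tr$start)
    unlink(p)
})

test_that("architecture interpretation maps segments onto assay features", {
    for (cls in c("inverted_duplication", "interstitial_deletion",
                  "translocation")) {
        run <- fxRun(cls)
        arch <- run$res$architecture
        if (cls == "inverted_duplication") {
            expect_identical(arch$boundaryFeature, "ura3-52")
            expect_true(arch$telomericRetention)
            expect_false(is.null(arch$duplicationExtent))
            ## duplication anchored in the breakpoint region
            expect_true(arch$consistent)
        } else if (cls == "interstitial_deletion") {
            expect_null(arch$duplicationExtent)
            ## deletion extent spans the cassette
            cass <- featureRange(fxChrom(), "URA3")
            del <- arch$deletionExtent
            expect_true(any(
                GenomicRanges::start(del) <= GenomicRanges::start(cass) &
                GenomicRanges::end(del) >= GenomicRanges::end(cass) - 500))
            expect_true(arch$telomericRetention)
        } else {
            ## whole telomeric arm lost
            expect_false(arch$telomericRetention)
            expect_null(arch$duplicationExtent)
        }
    }
    ## a duplication not anchored in the breakpoint region warns
    seg <- GenomicRanges::GRanges("assay_chrV",
                                  IRanges::IRanges(c(1, 20001, 30001),
                                                   c(20000, 30000, 50000)))
    S4Vectors::mcols(seg)$state <- c("neutral", "duplicated", "neutral")
    S4Vectors::mcols(seg)$meanLog2 <- c(0, 1, 0)
    S4Vectors::mcols(seg)$nProbes <- c(40L, 20L, 40L)
    expect_warning(arch <- interpretChrVLArchitecture(seg, fxChrom()),
                   "not anchored")
    expect_false(arch$consistent)
})

test_that("MLPA analysis calls amplified probes inside the duplication", {
    chrom <- fxChrom()
    control <- simulateMlpa(NULL, chrom, noiseCv = 0)
    ## identical tables: all ratios 1, nothing amplified
    self <- analyzeMlpa(control, control)
    expect_true(all(abs(self$ratio - 1) < 1e-12))
    expect_identical(length(self$amplified), 0L)
    ## product lengths form the documented 6 bp ladder
    expect_identical(unique(diff(control$product_length)), 6L)
    ## duplication from breakpoint region to ura3-52: amplified set is
    ## exactly the probes inside it (PCM1, VMA8, BUD16, GEA2 emulation)
    iso <- applyInvertedDuplication(chrom, 4000, 4200, 30, 5)
    sample <- simulateMlpa(iso, noiseCv = 0)
    res <- analyzeMlpa(sample, control)
    expect_setequal(res$amplified, c("PCM1", "VMA8", "BUD16", "GEA2"))
    ## the always-deleted cassette probe reads as deleted
    expect_true("YEL068C" %in% res$deleted)
    ## duplicated locus at exactly twice baseline without noise
    expect_identical(unname(res$ratio[["PCM1"]]), 2)
    expect_error(analyzeMlpa(sample[, c("probe", "peak_area")], control,
                             referenceProbes = character(0)), "reference")
})

test_that("MLPA amplification calls are specific under probe noise", {
    chrom <- fxChrom()
    clean <- 0L
    for (s in 1:100) {
        control <- simulateMlpa(NULL, chrom, noiseCv = 0.1, seed = 1000 + s)
        sample <- simulateMlpa(NULL, chrom, noiseCv = 0.1, seed = 2000 + s)
        res <- analyzeMlpa(sample, control)
        if (length(res$amplified) == 0L) clean <- clean + 1L
    }
    expect_gte(clean, 95L)
})

test_that("MLPA and aCGH agree on the duplication extent", {
    run <- fxRun("inverted_duplication")
    arch <- run$res$architecture
    mlpa <- run$res$mlpa
    probes <- defaultMlpaProbes(fxChrom())
    inDup <- probes$probe[
        probes$target_start >= GenomicRanges::start(arch$duplicationExtent) &
        probes$target_start <= GenomicRanges::end(arch$duplicationExtent)]
    expect_setequal(mlpa$amplified, inDup)
})
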