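test_that("locateJunction recovers constructed breakpoints and microhomology", {
    chrom <- fxChrom()
    ref <- as.character(chromSequence(chrom))
    ## concatenation fixture: ref[a-99..a] + ref[b..b+99] -> sides (a, b);
    ## b chosen so no chance flank identity blurs the split
    a <- 8000L; b <- 20000L
    while (substr(ref, a + 1, a + 1) == substr(ref, b, b) ||
           substr(ref, a, a) == substr(ref, b - 1, b - 1))
        b <- b + 1L
    cons <- paste0(substr(ref, a - 99, a), substr(ref, b, b + 99))
    ann <- locateJunction(cons, chrom)
    expect_identical(junctionClass(ann), "deletion")
    expect_identical(nchar(microhomologySeq(ann)), 0L)
    expect_identical(GenomicRanges::start(ann@sideA), a)
    expect_identical(GenomicRanges::start(ann@sideB), b)
    expect_identical(ann@insertSeq, "")
})

test_that("microhomology agrees with the brute-force oracle on random junctions", {
    set.seed(42)
    for (i in 1:200) {
        n <- 40L
        aSeq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
        bSeq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
        split <- sample(5:35, 1)
        got <- computeMicrohomology(aSeq, bSeq, split)
        expect_identical(got$length,
                         oracleMicrohomology(aSeq, bSeq, split))
        expect_identical(nchar(got$sequence), got$length)
    }
})

test_that("microhomology handles engineered, empty and capped cases", {
    a <- paste0(strrep("A", 10), "GATC", strrep("A", 10))
    b <- paste0(strrep("C", 10), "GATC", strrep("C", 10))
    got <- computeMicrohomology(a, b, 13)     # split inside GATC
    expect_identical(got$length, 4L)
    expect_identical(got$sequence, "GATC")
    ## completely distinct flanks
    expect_identical(computeMicrohomology(strrep("A", 20), strrep("C", 20),
                                          10)$length, 0L)
    ## palindromic/identical flank pathological case: capped and flagged
    same <- strrep("AC", 10)
    capped <- computeMicrohomology(same, same, 10)
    expect_identical(capped$length, 20L)
    expect_true(capped$capped)
})

test_that("engineered 4-base shared junction reports microhomology 4", {
    chrom <- fxChrom()
    iso <- applyInterstitialDeletion(chrom, 2150, 4650, microhomology = 4)
    ref <- as.character(chromSequence(refChromosome(iso)))
    co <- truth(iso)@coords
    cons <- paste0(substr(ref, co[["delStart"]] - 150, co[["delStart"]] - 1),
                   substr(ref, co[["delEnd"]] + 1, co[["delEnd"]] + 150))
    ann <- locateJunction(cons, refChromosome(iso))
    expect_identical(nchar(microhomologySeq(ann)), 4L)
    expect_identical(GenomicRanges::start(ann@sideA), co[["bpA"]])
    expect_identical(GenomicRanges::start(ann@sideB), co[["bpB"]])
    expect_identical(microhomologySeq(ann),
                     substr(ref, co[["delStart"]] - 4,
                            co[["delStart"]] - 1))
})

test_that("short or unmappable consensus sides degrade to unresolved", {
    chrom <- fxChrom()
    ref <- as.character(chromSequence(chrom))
    set.seed(3)
    random <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    ann <- locateJunction(paste0(random, substr(ref, 30000, 30119)), chrom)
    expect_identical(length(ann@sideA), 0L)
    expect_identical(junctionClass(ann), "unresolved")
    expect_error(locateJunction("ACGT", chrom), "40")
})

test_that("fold-back detection recovers engineered hairpin geometry exactly", {
    chrom <- fxChrom()
    iso <- applyInvertedDuplication(chrom, 4000, 4200, loop = 30,
                                    primingHomology = 5)
    co <- truth(iso)@coords
    prod <- as.character(productSeq(iso))
    armLen <- co[["dupEnd"]] - co[["dupStart"]] + 1L
    jStart <- co[["capturedEnd"]] + armLen
    cons <- substr(prod, jStart - 250, jStart + 280)
    fb <- detectFoldback(cons, refChromosome(iso))
    expect_false(is.null(fb))
    expect_identical(loopLength(fb), 30L)
    expect_identical(primingHomologyLength(fb), 5L)
    expect_identical(fb@loopStart, co[["loopStart"]])
    expect_identical(fb@center, co[["loopStart"]] + 15L)
    ## invariance under reverse complement of the consensus
    fb2 <- detectFoldback(gcrsig:::revcompStr(cons), refChromosome(iso))
    expect_identical(fb2@loopStart, fb@loopStart)
    expect_identical(loopLength(fb2), 30L)
    expect_identical(primingHomologyLength(fb2), 5L)
    ## no inverted repeat: returns NULL
    expect_null(detectFoldback(substr(prod, 100, 400),
                               refChromosome(iso)))
})

test_that("a perfect palindrome reports a zero-length loop", {
    chrom <- fxChrom()
    ref <- as.character(chromSequence(chrom))
    s0 <- 30000L
    arm <- substr(ref, s0, s0 + 119)
    cons <- paste0(gcrsig:::revcompStr(arm), arm)
    fb <- detectFoldback(cons, chrom)
    expect_false(is.null(fb))
    expect_identical(loopLength(fb), 0L)
})

test_that("TG1-3 conformity separates telomere seeds from random tails", {
    expect_true(detectTelomereAddition("TGTGGGTGTGGTGTGTGGG")$detected)
    expect_false(detectTelomereAddition("TGTGGG")$detected)  # too short
    set.seed(7)
    falseCalls <- 0L
    for (i in 1:1000) {
        tail <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
                      collapse = "")
        if (detectTelomereAddition(tail)$detected)
            falseCalls <- falseCalls + 1L
    }
    expect_lt(falseCalls / 1000, 0.01)
})

test_that("junction classification follows the priority order", {
    chrom <- fxChrom()
    ref <- as.character(chromSequence(chrom))
    delAnn <- locateJunction(paste0(substr(ref, 7901, 8000),
                                    substr(ref, 20000, 20099)), chrom)
    expect_identical(classifyJunction(delAnn), "deletion")
    ## fold-back evidence outranks a deletion-shaped placement
    fakeFb <- methods::new("FoldbackAnnotation", center = 1L,
                           loopStart = 1L, primingHomology = "AC",
                           loopSeq = "ACGT")
    expect_identical(classifyJunction(delAnn, foldback = fakeFb),
                     "inversion_foldback")
    expect_identical(classifyJunction(delAnn, foldback = fakeFb,
                                      telomere = list(detected = TRUE)),
                     "telomere_addition")
    ## cross-locus, strand-inconsistent placement is a translocation
    trAnn <- locateJunction(paste0(substr(ref, 7901, 8000),
                                   gcrsig:::revcompStr(
                                       substr(ref, 20000, 20099))), chrom)
    expect_identical(junctionClass(trAnn), "translocation")
})

test_that("end-to-end annotation reproduces truth for every event class", {
    for (cls in c("interstitial_deletion", "inverted_duplication",
                  "de_novo_telomere", "translocation")) {
        run <- fxRun(cls)
        res <- run$res
        tr <- truth(run$iso)
        expect_gte(length(res$annotations), 1L)
        co <- tr@coords
        classes <- vapply(res$annotations,
                          function(a) a$annotation@junctionClass,
                          character(1))
        if (cls == "interstitial_deletion") {
            i <- which(classes == "deletion")[1]
            ann <- res$annotations[[i]]$annotation
            expect_identical(GenomicRanges::start(ann@sideA), co[["bpA"]])
            expect_identical(GenomicRanges::start(ann@sideB), co[["bpB"]])
            expect_identical(nchar(microhomologySeq(ann)),
                             tr@microhomology)
        } else if (cls == "inverted_duplication") {
            i <- which(classes == "inversion_foldback")[1]
            fb <- res$annotations[[i]]$foldback
            expect_identical(loopLength(fb), tr@loop)
            expect_identical(primingHomologyLength(fb),
                             tr@primingHomology)
            expect_identical(fb@loopStart, co[["loopStart"]])
        } else if (cls == "de_novo_telomere") {
            i <- which(classes == "telomere_addition")[1]
            ann <- res$annotations[[i]]$annotation
            bp <- c(GenomicRanges::start(ann@sideA),
                    GenomicRanges::start(ann@sideB))
            expect_true(co[["pos"]] %in% bp)
        } else {
            i <- which(classes == "translocation")[1]
            ann <- res$annotations[[i]]$annotation
            bp <- sort(c(GenomicRanges::start(ann@sideA),
                         GenomicRanges::start(ann@sideB)))
            expect_identical(bp, sort(unname(co[c("pos", "donorEnd")])))
        }
    }
})
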