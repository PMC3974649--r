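test_that("interstitial deletion obeys length arithmetic and truth labels", {
    chrom <- fxChrom()
    L <- chromLength(chrom)
    iso <- applyInterstitialDeletion(chrom, 2100, 4600)
    expect_identical(length(productSeq(iso)), L - (4600L - 2100L + 1L))
    expect_identical(eventClass(iso), "interstitial_deletion")
    expect_true(truth(iso)@expectHph)
    ## a ~4 kb donor insert adds its length to the product
    tyFrag <- substr(featureSeq(chrom, "ura3-52"), 301, 800)
    ins <- paste(rep(tyFrag, 8), collapse = "")   # 4000 bp Ty-like fragment
    iso2 <- applyInterstitialDeletion(chrom, 2100, 4600, insert = ins)
    expect_identical(length(productSeq(iso2)),
                     L - (4600L - 2100L + 1L) + 4000L)
})

test_that("deletion microhomology is planted exactly, by string comparison", {
    chrom <- fxChrom()
    for (m in c(0L, 3L, 5L, 10L)) {
        iso <- applyInterstitialDeletion(chrom, 2150, 4650,
                                         microhomology = m)
        ref <- as.character(chromSequence(refChromosome(iso)))
        co <- truth(iso)@coords
        if (m > 0) {
            expect_identical(substr(ref, co[["delStart"]] - m,
                                    co[["delStart"]] - 1),
                             substr(ref, co[["delEnd"]] - m + 1,
                                    co[["delEnd"]]))
        }
        ## identity does not extend beyond m on either side
        expect_false(substr(ref, co[["delStart"]] - m - 1,
                            co[["delStart"]] - 1) ==
                     substr(ref, co[["delEnd"]] - m, co[["delEnd"]]))
        expect_false(substr(ref, co[["delStart"]], co[["delStart"]]) ==
                     substr(ref, co[["delEnd"]] + 1, co[["delEnd"]] + 1))
    }
})

test_that("unselectable or malformed deletions are rejected", {
    chrom <- fxChrom()
    expect_error(applyInterstitialDeletion(chrom, 4600, 2100), "precede")
    hph <- featureRange(chrom, "hph")
    expect_error(applyInterstitialDeletion(
        chrom, GenomicRanges::start(hph) - 50, 4600), "hph")
    pcm1 <- featureRange(chrom, "PCM1")
    expect_error(applyInterstitialDeletion(
        chrom, 2100, GenomicRanges::start(pcm1) + 50), "PCM1")
    expect_error(applyInterstitialDeletion(chrom, 5000, 6000), "cassette")
    expect_error(applyInterstitialDeletion(chrom, 2100, 4600,
                                           microhomology = 11), "0..10")
})

test_that("inverted duplication builds a palindrome with a loop spacer", {
    chrom <- fxChrom()
    iso <- applyInvertedDuplication(chrom, dsb = 4000, foldback = 4200,
                                    loop = 30, primingHomology = 5)
    tr <- truth(iso)
    expect_identical(tr@loop, 30L)
    expect_identical(tr@primingHomology, 5L)
    expect_identical(tr@expectSizeClass, "larger")
    expect_true(tr@expectHph)
    ## self-alignment oracle: junction +/- 200 bp vs its reverse complement
    prod <- as.character(productSeq(iso))
    co <- tr@coords
    ## locate the junction in product coordinates: captured fragment ends
    ## at capturedEnd, then the inverted arm of length dupEnd-dupStart+1
    armLen <- co[["dupEnd"]] - co[["dupStart"]] + 1L
    jStart <- co[["capturedEnd"]] + armLen      # last base of inverted arm
    win <- substr(prod, jStart - 200L, jStart + 200L + 30L)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
    ## the arms flanking the loop are mutual reverse complements
    arm1 <- substr(prod, jStart - 199L, jStart)
    arm2 <- substr(prod, jStart + 31L, jStart + 230L)
    expect_identical(arm1, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(arm2))))
    ## the 30-base spacer between the arms is not palindromic
    loopSeq <- substr(prod, jStart + 1L, jStart + 30L)
    expect_false(loopSeq == as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(loopSeq))))
    ## priming homology is templated in the reference, inverted, exactly 5
    ref <- as.character(chromSequence(refChromosome(iso)))
    lo <- co[["loopStart"]]; s <- co[["armStart"]]
    expect_identical(substr(ref, lo - 5, lo - 1),
                     gcrsig:::revcompStr(substr(ref, s, s + 4)))
    expect_false(substr(ref, lo - 6, lo - 6) ==
                 gcrsig:::revcompStr(substr(ref, s + 5, s + 5)))
})

test_that("resolution homology controls hph retention of inverted duplications", {
    chrom <- fxChrom()
    ura <- applyInvertedDuplication(chrom, 4000, 4100, 25, 4,
                                    resolution = "URA3/ura3-52")
    expect_true(truth(ura)@expectHph)
    expect_true(hphPresent(ura))
    none <- applyInvertedDuplication(chrom, 4000, 4100, 25, 4,
                                     resolution = "none")
    expect_false(truth(none)@expectHph)
    expect_false(hphPresent(none))
    tyty <- applyInvertedDuplication(chrom, 4000, 4100, 25, 4,
                                     resolution = "Ty/Ty")
    expect_false(truth(tyty)@expectHph)
    expect_false(hphPresent(tyty))
    expect_error(applyInvertedDuplication(chrom, 4000, 9990, 25, 4),
                 "absent")
})

test_that("full-scale inverted duplications reach the observed extents", {
    big <- fxBigChrom()
    iso <- applyInvertedDuplication(big, dsb = 31000, foldback = 31050,
                                    loop = 30, primingHomology = 5)
    co <- truth(iso)@coords
    delKb <- (co[["delEnd"]] - co[["delStart"]] + 1) / 1000
    dupKb <- (co[["dupEnd"]] - co[["dupStart"]] + 1) / 1000
    expect_true(delKb >= 4 && delKb <= 19)
    expect_true(dupKb >= 80 && dupKb <= 100)
})

test_that("de novo telomere products start with a TG1-3 tract and lose hph", {
    chrom <- fxChrom()
    bk <- featureRange(chrom, "GCR_breakpoint_region")
    pos <- GenomicRanges::start(bk) + 200L
    iso <- applyDeNovoTelomere(chrom, pos, seedRepeats = 25)
    prod <- as.character(productSeq(iso))
    tractLen <- nchar(truth(iso)@insertSeq)
    expect_gte(tractLen, 15L)
    ## regex oracle on the constructed product head
    expect_match(substr(prod, 1, tractLen), "^(TGGG|TGG|TG)+$")
    expect_false(hphPresent(iso))
    expect_false(truth(iso)@expectHph)
    ## degenerate and unselectable inputs
    expect_error(applyDeNovoTelomere(chrom, pos, seedRepeats = 0),
                 "positive")
    expect_error(applyDeNovoTelomere(chrom, 2300), "selectable")
})

test_that("translocations cap the arm with the donor and lose hph", {
    chrom <- fxChrom()
    bk <- featureRange(chrom, "GCR_breakpoint_region")
    pos <- GenomicRanges::start(bk) + 300L
    ref <- as.character(chromSequence(chrom))
    donor <- gcrsig:::revcompStr(substr(ref, 35000, 37999))
    iso <- applyTranslocation(chrom, pos, donor, "rc-donor")
    expect_identical(eventClass(iso), "translocation")
    expect_false(truth(iso)@expectHph)
    expect_identical(substr(as.character(productSeq(iso)), 1, 3000), donor)
    expect_error(applyTranslocation(chrom, pos, ""), "non-empty")
})

test_that("base composition is conserved up to the edited intervals", {
    chrom <- fxChrom()
    iso <- applyInterstitialDeletion(chrom, 2100, 4600, microhomology = 2)
    refFreq <- Biostrings::alphabetFrequency(
        chromSequence(refChromosome(iso)))[c("A", "C", "G", "T")]
    prodFreq <- Biostrings::alphabetFrequency(
        productSeq(iso))[c("A", "C", "G", "T")]
    co <- truth(iso)@coords
    delFreq <- Biostrings::alphabetFrequency(Biostrings::DNAString(
        substr(as.character(chromSequence(refChromosome(iso))),
               co[["delStart"]], co[["delEnd"]])))[c("A", "C", "G", "T")]
    expect_identical(prodFreq, refFreq - delFreq)
    ## inverted duplication: product = captured + revcomp(dup) + retained
    iso2 <- applyInvertedDuplication(chrom, 4000, 4200, 30, 5)
    ref2 <- as.character(chromSequence(refChromosome(iso2)))
    co2 <- truth(iso2)@coords
    sub <- function(a, b) Biostrings::alphabetFrequency(
        Biostrings::DNAString(substr(ref2, a, b)))[c("A", "C", "G", "T")]
    rcdup <- Biostrings::alphabetFrequency(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(ref2, co2[["dupStart"]],
                                     co2[["dupEnd"]]))))[c("A","C","G","T")]
    expected <- sub(1, co2[["capturedEnd"]]) + rcdup +
        sub(co2[["loopStart"]], nchar(ref2))
    expect_identical(Biostrings::alphabetFrequency(
        productSeq(iso2))[c("A", "C", "G", "T")], expected)
})

test_that("truth copy number reflects interval accounting", {
    chrom <- fxChrom()
    iso <- applyInvertedDuplication(chrom, 4000, 4200, 30, 5)
    cn <- truthCopyNumber(truth(iso), chromLength(chrom))
    co <- truth(iso)@coords
    expect_identical(unique(cn[co[["delStart"]]:co[["delEnd"]]]), 0L)
    expect_identical(unique(cn[co[["dupStart"]]:co[["dupEnd"]]]), 2L)
    expect_identical(unique(cn[1:co[["capturedEnd"]]]), 1L)
    expect_identical(unique(cn[(co[["dupEnd"]] + 1):chromLength(chrom)]), 1L)
})
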