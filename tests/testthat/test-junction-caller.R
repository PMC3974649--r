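test_that("SAM round-trip preserves pair count, mates and flags", {
    fx <- fxDeletionPairs()
    sam <- tempfile(fileext = ".sam")
    writeSam(fx$mapped, refChromosome(fx$iso), sam)
    loaded <- loadMappedPairs(sam)
    expect_identical(nrow(loaded), nrow(fx$mapped))
    m <- fx$mapped[order(fx$mapped$qname), ]
    expect_identical(loaded$r1_pos[loaded$r1_mapped],
                     m$r1_pos[m$r1_mapped])
    expect_identical(loaded$r1_unique, m$r1_unique)
    ## records with an unmapped mate are retained, flagged unmapped
    expect_identical(sum(!loaded$r2_mapped), sum(!m$r2_mapped))
    unlink(sam)
})

test_that("a SAM with zero pairs loads to an empty collection with a warning", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 "@SQ\tSN:assay_chrV\tLN:50000"), sam)
    expect_warning(out <- loadMappedPairs(sam), "no read pairs")
    expect_identical(nrow(out), 0L)
    expect_error(loadMappedPairs(tempfile()), "no such SAM")
    unlink(sam)
})

test_that("deduplication retains one representative per coordinate tuple", {
    chrom <- fxChrom()
    pairs <- simulateReadPairs(chrom, libraryModel(coverage = 10,
                                                   dupFraction = 0.2,
                                                   seed = 13))
    mapped <- mapPairsToReference(pairs, chrom)
    dd <- deduplicatePairs(mapped)
    expect_identical(nrow(dd), attr(pairs, "uniqueTruthCount"))
    ## idempotence
    expect_identical(deduplicatePairs(dd), dd)
    ## pairs identical in one mate only are both retained
    two <- mapped[1:2, ]
    two$qname <- c("x", "y")
    two$r1_pos <- c(100L, 100L)
    two$r1_strand <- "+"
    two$r2_pos <- c(600L, 700L)
    expect_identical(nrow(deduplicatePairs(two)), 2L)
})

test_that("nread and nspan satisfy their counting identities", {
    chrom <- fxChrom()
    pairs <- simulateReadPairs(chrom, libraryModel(coverage = 5, seed = 17))
    mapped <- mapPairsToReference(pairs, chrom)
    dd <- deduplicatePairs(mapped)
    use <- dd[dd$r1_unique & dd$r2_unique, ]
    tracks <- computeCoverageTracks(dd, chromLength(chrom))
    expect_identical(sum(tracks$nread), 2L * nrow(use) * 100L)
    spans <- pmax(use$r1_pos, use$r2_pos) + 99L -
        pmin(use$r1_pos, use$r2_pos) + 1L
    expect_identical(sum(tracks$nspan), sum(spans))
    ## a single 600 bp-span pair covers exactly 600 bases once
    one <- use[1, ]
    t1 <- computeCoverageTracks(one, chromLength(chrom))
    expect_identical(sum(t1$nspan > 0),
                     as.integer(pmax(one$r1_pos, one$r2_pos) + 99 -
                                pmin(one$r1_pos, one$r2_pos) + 1))
})

test_that("insert statistics recover the library and set the cutoff", {
    fx <- fxDeletionPairs()
    st <- estimateInsertStats(deduplicatePairs(fx$mapped))
    expect_lt(abs(st$median - 600) / 600, 0.02)
    expect_identical(st$cutoff, st$median + 10 * st$mad)
    ## degenerate: all pairs at one distance
    mk <- fx$mapped[fx$mapped$r1_unique & fx$mapped$r2_unique, ][1:200, ]
    mk$r1_pos <- seq_len(200) * 10L
    mk$r1_strand <- "+"
    mk$r2_pos <- mk$r1_pos + 400L
    mk$r2_strand <- "-"
    st2 <- estimateInsertStats(mk)
    expect_identical(st2$median, 500)
    expect_identical(st2$mad, 0)
    expect_error(estimateInsertStats(mk[1:50, ]), "cutoff")
})

test_that("clustering finds the deletion junction and nothing on concordant data", {
    fx <- fxDeletionPairs()
    dd <- deduplicatePairs(fx$mapped)
    st <- estimateInsertStats(dd)
    calls <- clusterJunctionPairs(dd, st, targetLength = 50000)
    sig <- Filter(isSignificant, calls)
    expect_identical(length(sig), 1L)
    call <- sig[[1]]
    co <- truth(fx$iso)@coords
    ## side intervals bracket the true breakpoints to read resolution
    ## (base-exact placement is the consensus annotation's job)
    expect_true(GenomicRanges::start(call@sideA) <= co[["bpA"]] &&
                GenomicRanges::end(call@sideA) >= co[["bpA"]] - 30L)
    expect_true(GenomicRanges::end(call@sideB) >= co[["bpB"]] &&
                GenomicRanges::start(call@sideB) <= co[["bpB"]] + 30L)
    ## concordant-only library yields zero calls
    chrom <- fxChrom()
    conc <- mapPairsToReference(
        simulateReadPairs(chrom, libraryModel(coverage = 10, seed = 19)),
        chrom)
    calls0 <- clusterJunctionPairs(deduplicatePairs(conc),
                                   estimateInsertStats(conc),
                                   targetLength = 50000)
    expect_identical(length(calls0), 0L)
})

test_that("fold-back pairs cluster with same-orientation geometry", {
    run <- fxRun("inverted_duplication")
    sig <- run$res$significantCalls
    geoms <- vapply(sig, function(x) x@geometry, character(1))
    expect_true("foldback" %in% geoms)
    fb <- sig[[which(geoms == "foldback")[1]]]
    expect_identical(as.character(GenomicRanges::strand(fb@sideA)),
                     as.character(GenomicRanges::strand(fb@sideB)))
    ## the fold-back call flanks the fold-back point
    lo <- truth(run$iso)@coords[["loopStart"]]
    expect_lt(abs(GenomicRanges::end(fb@sideA) - lo), 1500)
})

test_that("recruited junction reads truly span the junction", {
    fx <- fxDeletionPairs()
    dd <- deduplicatePairs(fx$mapped)
    st <- estimateInsertStats(dd)
    call <- Filter(isSignificant,
                   clusterJunctionPairs(dd, st, targetLength = 50000))[[1]]
    reads <- recruitJunctionReads(call, dd, st)
    expect_gt(length(reads), 0)
    ## every recruited read is a junction-spanning product substring that
    ## does not occur in the reference
    prod <- as.character(productSeq(fx$iso))
    ref <- as.character(chromSequence(refChromosome(fx$iso)))
    for (r in reads) {
        hit <- grepl(r, prod, fixed = TRUE) ||
            grepl(gcrsig:::revcompStr(r), prod, fixed = TRUE)
        expect_true(hit)
        expect_false(grepl(r, ref, fixed = TRUE) ||
                     grepl(gcrsig:::revcompStr(r), ref, fixed = TRUE))
    }
    ## a call with no nearby half-mapped pairs recruits nothing
    far <- methods::new("JunctionCall",
        sideA = GenomicRanges::GRanges("assay_chrV",
                                       IRanges::IRanges(40000, 40100),
                                       strand = "+"),
        sideB = GenomicRanges::GRanges("assay_chrV",
                                       IRanges::IRanges(45000, 45100),
                                       strand = "-"),
        geometry = "cross", supportIds = "q1", support = 1L,
        pvalue = 1, significant = FALSE)
    expect_identical(length(recruitJunctionReads(far, dd, st)), 0L)
})

test_that("greedy consensus assembly reconstructs a known junction exactly", {
    ## staggered error-free reads tiling a known 400 bp sequence
    set.seed(1)
    junction <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                      collapse = "")
    starts <- seq(1, 301, by = 20)
    reads <- substring(junction, starts, starts + 99)
    cons <- assembleJunctionConsensus(reads)
    expect_identical(consensusSeq(cons), junction)
    expect_identical(cons@nReads, length(reads))
    expect_identical(cons@agreement, 1)
    ## reverse-complemented reads are oriented automatically
    mixed <- reads
    mixed[c(2, 5, 9)] <- vapply(mixed[c(2, 5, 9)], gcrsig:::revcompStr,
                                character(1))
    cons2 <- assembleJunctionConsensus(mixed)
    expect_true(consensusSeq(cons2) == junction ||
                consensusSeq(cons2) == gcrsig:::revcompStr(junction))
    ## all reads identical: consensus equals the read
    cons3 <- assembleJunctionConsensus(rep(reads[1], 5))
    expect_identical(consensusSeq(cons3), reads[1])
    ## unjoinable reads leave the largest layout with a warning
    expect_warning(
        cons4 <- assembleJunctionConsensus(c(junction,
                                             strrep("ACGTT", 30))),
        "could not be joined")
    expect_identical(consensusSeq(cons4), junction)
    expect_error(assembleJunctionConsensus(character(0)), "at least one")
})
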