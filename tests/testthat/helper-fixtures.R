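# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fxCached <- function(key, builder) {
    if (is.null(.fx[[key]])) .fx[[key]] <- builder()
    .fx[[key]]
}

fxChrom <- function() fxCached("chrom", function()
    buildAssayChromosome(length = 50000, seed = 1))

fxBigChrom <- function() fxCached("big", function()
    buildAssayChromosome(length = 580000, seed = 2))

# one fully analysed isolate per event class (50 kb, 50x, error-free)
fxRun <- function(class) fxCached(paste0("run_", class), function() {
    iso <- drawIsolate(fxChrom(), class, seed = 42)
    list(iso = iso,
         res = runIsolate(iso, libraryModel(seed = 7), id = class))
})

fxDeletionPairs <- function() fxCached("delpairs", function() {
    iso <- fxRun("interstitial_deletion")$iso
    pairs <- simulateReadPairs(iso, libraryModel(seed = 7))
    mapped <- mapPairsToReference(pairs, refChromosome(iso))
    list(iso = iso, pairs = pairs, mapped = mapped)
})

# brute-force oracle: maximal contiguous identity across a split
oracleMicrohomology <- function(aSeq, bSeq, split) {
    n <- nchar(aSeq)
    best <- 0L
    for (lo in seq_len(split)) {
        for (hi in seq(split - 1L, n)) {
            if (hi < lo) next
            if (substr(aSeq, lo, hi) == substr(bSeq, lo, hi) &&
                lo <= split && hi >= split - 1L)
                best <- max(best, hi - lo + 1L)
        }
    }
    best
}

# enumeration oracle for the exact two-tailed Mann-Whitney p-value
oracleMannWhitneyP <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    allR <- rank(seq_len(n1 + n2))
    us <- apply(combos, 2L, function(idx)
        sum(allR[idx]) - n1 * (n1 + 1) / 2)
    lowTail <- mean(us <= min(U, n1 * n2 - U))
    min(1, 2 * lowTail)
}
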