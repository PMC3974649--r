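# Internal helpers shared across modules.

#' @importFrom methods new is validObject slot
#' @importFrom stats median mad rnorm runif rpois pchisq ppois uniroot
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards.  All simulators route their randomness
## through this so that a single integer seed fixes every draw.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    force(expr)
}

## Fan a global seed out to per-stage seeds, keeping results < 2^31.
fanSeed <- function(seed, stage) {
    (as.numeric(seed) * 1009 + as.numeric(stage) * 9973) %% 2147483647
}

randDnaChars <- function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

randDna <- function(n) paste(randDnaChars(n), collapse = "")

revcompStr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Longest common prefix length of two character scalars (vectorised over
## single bases internally).
lcpLength <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    if (n == 0L) return(0L)
    av <- substring(a, seq_len(n), seq_len(n))
    bv <- substring(b, seq_len(n), seq_len(n))
    mism <- which(av != bv)
    if (length(mism) == 0L) n else mism[1L] - 1L
}

## Longest common suffix length.
lcsLength <- function(a, b) {
    lcpLength(paste(rev(strsplit(a, "")[[1L]]), collapse = ""),
              paste(rev(strsplit(b, "")[[1L]]), collapse = ""))
}

## Replace substring [at, at+nchar(value)-1] of x with value.
strAssign <- function(x, at, value) {
    paste0(substr(x, 1L, at - 1L), value,
           substr(x, at + nchar(value), nchar(x)))
}

## A base different from `base` (deterministic choice).
otherBase <- function(base) {
    c(A = "C", C = "A", G = "T", T = "G")[[toupper(base)]]
}

## TG1-3 telomere-seed tract: a mixture of TG/TGG/TGGG units, mimicking the
## irregular yeast telomeric repeat. Returns at least minWidth characters
## when minWidth is given.
tgTract <- function(nUnits, minWidth = 0L) {
    units <- sample(c("TG", "TGG", "TGGG"), nUnits,
                    replace = TRUE, prob = c(0.4, 0.35, 0.25))
    tract <- paste(units, collapse = "")
    while (nchar(tract) < minWidth) {
        tract <- paste0(tract, sample(c("TG", "TGG", "TGGG"), 1L))
    }
    tract
}

## Remove every occurrence of `motif` from x except at allowed positions, by
## mutating the middle base of the offending occurrence.
scrubMotif <- function(x, motif, allowedStarts = integer(0)) {
    repeat {
        hits <- Biostrings::start(Biostrings::matchPattern(
            Biostrings::DNAString(motif), Biostrings::DNAString(x)))
        bad <- setdiff(hits, allowedStarts)
        if (length(bad) == 0L) return(x)
        at <- bad[1L] + nchar(motif) %/% 2L
        x <- strAssign(x, at, otherBase(substr(x, at, at)))
    }
}
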