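#' @include rearrangements.R
NULL

#' Paired-end library model constructor
#'
#' Defaults emulate the 600 bp gel-fractionated paired-end library used for
#' whole-genome sequencing of GCR isolates.
#'
#' @param insertMean,insertSd fragment size mean and sd in bp.
#' @param readLength read length in bp.
#' @param coverage fold coverage.
#' @param dupFraction fraction of pairs that are exact (PCR/optical-style)
#'   duplicates of earlier pairs.
#' @param seed RNG seed.
#' @return a \linkS4class{LibraryModel}.
#' @export
libraryModel <- function(insertMean = 600, insertSd = 60, readLength = 100L,
                         coverage = 50, dupFraction = 0, seed = 1L) {
    new("LibraryModel", insertMean = insertMean, insertSd = insertSd,
        readLength = as.integer(readLength), coverage = coverage,
        dupFraction = dupFraction, seed = as.integer(seed))
}

#' Simulate an error-free paired-end read library
#'
#' Fragments are drawn uniformly along the genome with normal insert sizes
#' (truncated below at the read length); both ends are reported in
#' convergent orientation.  A \code{dupFraction} of pairs are exact copies
#' of earlier pairs, matching PCR/optical duplicate semantics used by
#' coordinate-based deduplication.  Deterministic under the model seed.
#'
#' @param genome a \linkS4class{DNAString}, \linkS4class{RearrangedIsolate}
#'   or \linkS4class{AssayChromosome} to sequence.
#' @param model a \linkS4class{LibraryModel}.
#' @return a \code{data.frame} with one row per pair (qname, fragStart,
#'   fragEnd, seq1, seq2, isDup) and attributes \code{genomeLength},
#'   \code{readLength} and \code{uniqueTruthCount}.
#' @export
simulateReadPairs <- function(genome, model = libraryModel()) {
    if (is(genome, "RearrangedIsolate")) genome <- productSeq(genome)
    if (is(genome, "AssayChromosome")) genome <- chromSequence(genome)
    stopifnot(is(genome, "DNAString"), is(model, "LibraryModel"))
    validObject(model)
    L <- length(genome)
    if (L <= 2 * model@insertMean)
        stop("genome must be longer than twice the insert mean")
    rl <- model@readLength
    nPairs <- round(model@coverage * L / (2 * rl))
    nDup <- round(model@dupFraction * nPairs)
    nUnique <- nPairs - nDup
    gseq <- as.character(genome)

    df <- withSeed(model@seed, {
        len <- pmax(rl, pmin(L, round(rnorm(nUnique, model@insertMean,
                                            model@insertSd))))
        start <- floor(runif(nUnique, 1, L - len + 1))
        frag <- data.frame(fragStart = as.integer(start),
                           fragEnd = as.integer(start + len - 1L),
                           isDup = FALSE)
        if (nDup > 0L) {
            src <- sample.int(nUnique, nDup, replace = TRUE)
            dup <- frag[src, , drop = FALSE]
            dup$isDup <- TRUE
            frag <- rbind(frag, dup)
        }
        frag
    })
    df$qname <- sprintf("pair%06d", seq_len(nrow(df)))
    df$seq1 <- substring(gseq, df$fragStart, df$fragStart + rl - 1L)
    df$seq2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(substring(gseq, df$fragEnd - rl + 1L,
                                           df$fragEnd))))
    df <- df[, c("qname", "fragStart", "fragEnd", "seq1", "seq2", "isDup")]
    attr(df, "genomeLength") <- L
    attr(df, "readLength") <- rl
    attr(df, "uniqueTruthCount") <-
        nrow(unique(df[, c("fragStart", "fragEnd")]))
    df
}

## Exact-match alignment of equal-width reads against a reference, both
## strands.  Returns pos (leftmost base, 1-based), strand, and hit count
## (genome-wide, both strands); unique mapping means exactly one hit.
mapReadSet <- function(seqs, refSeq) {
    rl <- unique(nchar(seqs))
    stopifnot(length(rl) == 1L)
    L <- length(refSeq)
    reads <- Biostrings::DNAStringSet(seqs)
    pd <- Biostrings::PDict(reads)
    fwd <- Biostrings::matchPDict(pd, refSeq)
    rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(refSeq))
    sF <- Biostrings::startIndex(fwd)
    sR <- Biostrings::startIndex(rev)
    nF <- lengths(sF)
    nR <- lengths(sR)
    nhits <- nF + nR
    pos <- rep(NA_integer_, length(seqs))
    strand <- rep(NA_character_, length(seqs))
    oneF <- which(nF == 1L & nR == 0L)
    oneR <- which(nR == 1L & nF == 0L)
    pos[oneF] <- unlist(sF[oneF], use.names = FALSE)
    strand[oneF] <- "+"
    ## leftmost coordinate on the forward reference for a minus-strand hit
    pos[oneR] <- L - (unlist(sR[oneR], use.names = FALSE) + rl - 1L) + 1L
    strand[oneR] <- "-"
    ## multimappers: report the first forward hit (flagged non-unique)
    multi <- which(nhits > 1L)
    for (i in multi) {
        if (nF[i] > 0L) {
            pos[i] <- sF[[i]][1L]; strand[i] <- "+"
        } else {
            pos[i] <- L - (sR[[i]][1L] + rl - 1L) + 1L; strand[i] <- "-"
        }
    }
    data.frame(pos = pos, strand = strand, nhits = nhits)
}

#' Map simulated read pairs to the assay reference
#'
#' Exact-match alignment (both strands) of the simulated error-free reads
#' against the reference chromosome.  A read is mapped when it matches at
#' least once and uniquely mapping when it matches exactly once genome-wide;
#' junction-spanning reads match nowhere and are reported unmapped.
#'
#' @param pairs output of \code{\link{simulateReadPairs}}.
#' @param reference an \linkS4class{AssayChromosome}.
#' @return a \code{data.frame} of \code{MappedPair} records with per-mate
#'   columns (rname, pos, strand, mapped, unique, seq).
#' @export
mapPairsToReference <- function(pairs, reference) {
    stopifnot(is(reference, "AssayChromosome"))
    refSeq <- chromSequence(reference)
    m1 <- mapReadSet(pairs$seq1, refSeq)
    m2 <- mapReadSet(pairs$seq2, refSeq)
    data.frame(
        qname = pairs$qname,
        r1_rname = ifelse(is.na(m1$pos), NA_character_,
                          chromName(reference)),
        r1_pos = m1$pos, r1_strand = m1$strand,
        r1_mapped = !is.na(m1$pos), r1_unique = m1$nhits == 1L,
        r1_seq = pairs$seq1,
        r2_rname = ifelse(is.na(m2$pos), NA_character_,
                          chromName(reference)),
        r2_pos = m2$pos, r2_strand = m2$strand,
        r2_mapped = !is.na(m2$pos), r2_unique = m2$nhits == 1L,
        r2_seq = pairs$seq2)
}

.samFlag <- function(first, mapped, mateMapped, strand, mateStrand) {
    flag <- 1L                                   # paired
    if (!mapped) flag <- flag + 4L
    if (!mateMapped) flag <- flag + 8L
    if (mapped && identical(strand, "-")) flag <- flag + 16L
    if (mateMapped && identical(mateStrand, "-")) flag <- flag + 32L
    flag + if (first) 64L else 128L
}

#' Write mapped pairs as SAM
#'
#' Emits a coordinate-unsorted SAM file with an \code{@SQ} header for the
#' assay chromosome.  Uniquely mapping reads get MAPQ 42, multimappers
#' MAPQ 0, so the MAPQ >= 20 uniqueness dialect round-trips.
#'
#' @param mapped output of \code{\link{mapPairsToReference}}.
#' @param reference the \linkS4class{AssayChromosome} mapped against.
#' @param path output SAM path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(mapped, reference, path) {
    rl <- nchar(mapped$r1_seq[1L])
    rn <- chromName(reference)
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", rn, chromLength(reference)))
    rec <- function(first) {
        p <- if (first) "r1" else "r2"
        q <- if (first) "r2" else "r1"
        g <- function(df, col) df[[paste0(p, "_", col)]]
        gm <- function(df, col) df[[paste0(q, "_", col)]]
        flags <- mapply(.samFlag, first, g(mapped, "mapped"),
                        gm(mapped, "mapped"), g(mapped, "strand"),
                        gm(mapped, "strand"))
        mapq <- ifelse(!g(mapped, "mapped"), 0L,
                       ifelse(g(mapped, "unique"), 42L, 0L))
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                mapped$qname, flags,
                ifelse(g(mapped, "mapped"), rn, "*"),
                ifelse(g(mapped, "mapped"), g(mapped, "pos"), 0L),
                mapq,
                ifelse(g(mapped, "mapped"), paste0(rl, "M"), "*"),
                ifelse(gm(mapped, "mapped"), "=", "*"),
                ifelse(gm(mapped, "mapped"), gm(mapped, "pos"), 0L),
                g(mapped, "seq"),
                strrep("I", rl))
    }
    writeLines(c(hdr, rec(TRUE), rec(FALSE)), path)
    invisible(path)
}

#' Write a simulated library as paired FASTQ plus a truth SAM
#'
#' The truth SAM records each read's true origin on the rearranged genome.
#'
#' @param pairs output of \code{\link{simulateReadPairs}}.
#' @param prefix output path prefix; writes \code{<prefix>_1.fastq},
#'   \code{<prefix>_2.fastq} and \code{<prefix>_truth.sam}.
#' @param genomeName name for the rearranged genome in the truth SAM.
#' @return the three paths, invisibly.
#' @export
writeFastqPair <- function(pairs, prefix, genomeName = "rearranged") {
    rl <- attr(pairs, "readLength")
    L <- attr(pairs, "genomeLength")
    qual <- strrep("I", rl)
    fq <- function(seqs, tag) {
        as.vector(rbind(paste0("@", pairs$qname, "/", tag),
                        seqs, "+", qual))
    }
    p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
    ps <- paste0(prefix, "_truth.sam")
    writeLines(fq(pairs$seq1, "1"), p1)
    writeLines(fq(pairs$seq2, "2"), p2)
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", genomeName, L))
    r2pos <- pairs$fragEnd - rl + 1L
    rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                    pairs$qname, genomeName, pairs$fragStart, rl, r2pos,
                    pairs$fragEnd - pairs$fragStart + 1L, pairs$seq1, qual)
    rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                    pairs$qname, genomeName, r2pos, rl, pairs$fragStart,
                    -(pairs$fragEnd - pairs$fragStart + 1L), pairs$seq2, qual)
    writeLines(c(hdr, rec1, rec2), ps)
    invisible(c(p1, p2, ps))
}
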