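#' @include pipeline.R
NULL

#' Write junction calls as breakend VCF plus a TSV sidecar
#'
#' Each junction call is emitted as a pair of BND-style breakend records
#' (one per side); support, significance and geometry go to an
#' accompanying TSV.
#'
#' @param calls list of \linkS4class{JunctionCall} objects.
#' @param reference the \linkS4class{AssayChromosome} called against.
#' @param prefix output path prefix; writes \code{<prefix>.vcf} and
#'   \code{<prefix>.tsv}.
#' @return the two paths, invisibly.
#' @export
writeJunctionCalls <- function(calls, reference, prefix) {
    vcf <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chromName(reference),
                     chromLength(reference)),
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting pairs\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
    tsv <- "id\tgeometry\tsideA\tsideB\tstrandA\tstrandB\tsupport\tpvalue\tsignificant"
    refStr <- as.character(chromSequence(reference))
    for (i in seq_along(calls)) {
        call <- calls[[i]]
        idA <- sprintf("bnd_%d_A", i)
        idB <- sprintf("bnd_%d_B", i)
        posA <- GenomicRanges::start(call@sideA)
        posB <- GenomicRanges::start(call@sideB)
        rn <- chromName(reference)
        baseA <- substr(refStr, posA, posA)
        baseB <- substr(refStr, posB, posB)
        strandB <- as.character(GenomicRanges::strand(call@sideB))
        altA <- if (strandB == "+")
            sprintf("%s[%s:%d[", baseA, rn, posB)
        else sprintf("%s]%s:%d]", baseA, rn, posB)
        strandA <- as.character(GenomicRanges::strand(call@sideA))
        altB <- if (strandA == "+")
            sprintf("]%s:%d]%s", rn, posA, baseB)
        else sprintf("[%s:%d[%s", rn, posA, baseB)
        flt <- if (call@significant) "PASS" else "low_support"
        vcf <- c(vcf,
            sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tSVTYPE=BND;MATEID=%s;SUPPORT=%d",
                    rn, posA, idA, baseA, altA, flt, idB, call@support),
            sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tSVTYPE=BND;MATEID=%s;SUPPORT=%d",
                    rn, posB, idB, baseB, altB, flt, idA, call@support))
        tsv <- c(tsv, sprintf("call%d\t%s\t%d\t%d\t%s\t%s\t%d\t%.4g\t%s",
                              i, call@geometry, posA, posB,
                              strandA, strandB,
                              call@support, call@pvalue,
                              call@significant))
    }
    vp <- paste0(prefix, ".vcf"); tp <- paste0(prefix, ".tsv")
    writeLines(vcf, vp)
    writeLines(tsv, tp)
    invisible(c(vp, tp))
}

#' Write the per-isolate and summary tables of a cohort report
#'
#' Emits the per-isolate classification TSV, the duplication-by-hph
#' two-way summary, the retention table, and a JSON evidence bundle per
#' isolate (truth class, called class, junction classes, architecture and
#' PFGE size class).
#'
#' @param report output of \code{\link{runCohort}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohortReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(report$summary,
                       file.path(dir, "classifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$twoWay,
                       file.path(dir, "duplication_by_hph.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$retention,
                       file.path(dir, "retention.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle <- lapply(report$results, function(r) {
        list(id = r$id,
             truthClass = r$truth@eventClass,
             calledClass = r$classification@gcrClass,
             hph = r$hph,
             junctionClasses = vapply(
                 r$annotations, function(a) a$annotation@junctionClass,
                 character(1)),
             sizeClass = r$digest$sizeClass,
             boundaryFeature = r$architecture$boundaryFeature,
             mlpaAmplified = r$mlpa$amplified)
    })
    jsonlite::write_json(bundle, file.path(dir, "evidence.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' Write consensus sequences as FASTA
#'
#' @param consensuses named list of \linkS4class{JunctionSequence} or
#'   character sequences.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeConsensusFasta <- function(consensuses, path) {
    seqs <- vapply(consensuses, function(x) {
        if (is(x, "JunctionSequence")) consensusSeq(x) else as.character(x)
    }, character(1))
    nm <- names(seqs) %||% sprintf("junction%d", seq_along(seqs))
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- nm
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Write reference and rearranged genomes as FASTA
#'
#' @param isolate a \linkS4class{RearrangedIsolate} or
#'   \linkS4class{AssayChromosome}.
#' @param path output FASTA path.
#' @param name sequence name.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(isolate, path, name = NULL) {
    if (is(isolate, "RearrangedIsolate")) {
        seq <- productSeq(isolate)
        name <- name %||% "rearranged"
    } else {
        seq <- chromSequence(isolate)
        name <- name %||% chromName(isolate)
    }
    set <- Biostrings::DNAStringSet(as.character(seq))
    names(set) <- name
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Write the feature map as 6-column BED (0-based half-open)
#'
#' @param chrom an \linkS4class{AssayChromosome}.
#' @param path output BED path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureBed <- function(chrom, path) {
    feats <- chromFeatures(chrom)
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       chromName(chrom),
                       GenomicRanges::start(feats) - 1L,
                       GenomicRanges::end(feats),
                       names(feats),
                       ifelse(as.character(
                           GenomicRanges::strand(feats)) == "*",
                           ".", as.character(GenomicRanges::strand(feats)))),
               path)
    invisible(path)
}
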