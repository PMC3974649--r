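#' @include pfge.R copyNumber.R junctionAnnotator.R
NULL

#' Integrate junction, copy-number, marker and PFGE evidence into a GCR
#' class
#'
#' Decision rules, with junction evidence taking precedence over
#' copy-number evidence (junction sequence is base-resolution):
#' \itemize{
#'   \item a fold-back inversion junction, or a duplication anchored in
#'     the GCR breakpoint region together with a larger-than-wild-type
#'     chromosome, implies an inverted duplication (resolution homology
#'     from the architecture's centromeric boundary feature);
#'   \item a deletion junction with no duplication and a similar-or-smaller
#'     chromosome implies an interstitial deletion;
#'   \item a telomere-addition junction implies a de novo telomere;
#'   \item a junction joining distant or strand-inconsistent loci (with no
#'     duplication evidence) implies a translocation;
#'   \item more than one independent duplication implies a complex event;
#'   \item conflicting evidence (e.g. duplication with a similar size
#'     class) is unclassified with notes.
#' }
#'
#' @param annotations list of junction annotation results (as returned by
#'   \code{\link{annotateJunction}}), possibly empty.
#' @param architecture a \code{ChrVLArchitecture} or NULL.
#' @param digest a \code{PFGEDigest} or NULL.
#' @param hph logical: is the hph marker present?
#' @param isolate isolate id.
#' @return a \linkS4class{GCRClassification}.
#' @export
classifyGcr <- function(annotations = list(), architecture = NULL,
                        digest = NULL, hph = NA, isolate = "isolate") {
    if (length(annotations) == 0L && is.null(architecture) &&
        is.null(digest))
        stop("at least one evidence source is required")
    jClasses <- vapply(annotations,
                       function(x) x$annotation@junctionClass,
                       character(1))
    hasFoldback <- any(jClasses == "inversion_foldback")
    hasTelomere <- any(jClasses == "telomere_addition")
    hasDeletion <- any(jClasses == "deletion")
    hasTransloc <- any(jClasses == "translocation")

    nDup <- 0L
    dupAnchored <- FALSE
    boundary <- "none"
    if (!is.null(architecture)) {
        nDup <- architecture$nDuplications %||%
            (if (is.null(architecture$duplicationExtent)) 0L else 1L)
        dupAnchored <- nDup > 0L && architecture$consistent
        boundary <- architecture$boundaryFeature
    }
    sizeClass <- if (!is.null(digest)) digest$sizeClass else NA_character_
    notes <- character(0)

    cls <- if (hasFoldback ||
               (dupAnchored && identical(sizeClass, "larger"))) {
        if (nDup > 1L) "complex" else "inverted_duplication"
    } else if (hasTelomere) {
        "de_novo_telomere"
    } else if (hasDeletion && nDup == 0L &&
               (is.na(sizeClass) || sizeClass != "larger")) {
        "interstitial_deletion"
    } else if (hasTransloc && nDup == 0L) {
        "translocation"
    } else if (nDup > 0L && identical(sizeClass, "similar")) {
        notes <- c(notes, "duplication evidence conflicts with a ",
                   "wild-type-like chromosome size")
        "unclassified"
    } else if (nDup > 0L) {
        "inverted_duplication"
    } else {
        notes <- c(notes, "no decisive evidence")
        "unclassified"
    }
    if (cls == "inverted_duplication" && hasFoldback && nDup == 0L)
        ## junction evidence alone; trust base-resolution geometry
        nDup <- 1L
    if (cls != "inverted_duplication") boundary <- "none"
    new("GCRClassification", isolate = isolate, gcrClass = cls,
        hphRetained = as.logical(hph), chrVLDuplication = nDup > 0L,
        resolution = boundary,
        notes = paste(notes, collapse = ""))
}

#' @rdname accessors
#' @export
setMethod("gcrClass", "GCRClassification", function(x) x@gcrClass)
#' @rdname accessors
#' @export
setMethod("hphRetained", "GCRClassification", function(x) x@hphRetained)

setMethod("show", "GCRClassification", function(object) {
    cat(sprintf(
        "GCRClassification %s: %s (hph %s, chrV L duplication %s%s)\n",
        object@isolate, object@gcrClass,
        if (isTRUE(object@hphRetained)) "retained" else "lost",
        if (object@chrVLDuplication) "yes" else "no",
        if (object@resolution != "none")
            paste0(", resolved via ", object@resolution) else ""))
    if (nzchar(object@notes)) cat("  notes:", object@notes, "\n")
})

.retentionPercent <- function(retaining, total) {
    pct <- 100 * retaining / total
    if (pct == 0) 0 else if (pct >= 1) round(pct) else signif(pct, 1)
}

#' Tabulate hph retention per genotype
#'
#' Per-genotype retaining counts, totals and percent retention following
#' the reporting convention of the assay literature: integer percent at or
#' above 1\%, one significant figure below 1\%.
#'
#' @param x either a \code{data.frame} with columns \code{genotype} and
#'   \code{retained} (logical, one row per isolate), or one with columns
#'   \code{genotype}, \code{retaining}, \code{total} (pre-counted).
#' @return a \code{data.frame} with genotype, retaining, total, percent.
#' @export
tabulateRetention <- function(x) {
    if (all(c("retaining", "total") %in% names(x))) {
        df <- x[, c("genotype", "retaining", "total")]
    } else {
        stopifnot(all(c("genotype", "retained") %in% names(x)))
        empty <- setdiff(unique(x$genotype),
                         unique(x$genotype[!is.na(x$retained)]))
        if (length(empty) > 0L)
            warning("omitting genotypes without scored isolates: ",
                    paste(empty, collapse = ", "))
        x <- x[!is.na(x$retained), , drop = FALSE]
        agg <- aggregate(retained ~ genotype, data = x,
                         FUN = function(v) c(sum(v), length(v)))
        df <- data.frame(genotype = agg$genotype,
                         retaining = agg$retained[, 1L],
                         total = agg$retained[, 2L])
    }
    stopifnot(all(df$retaining >= 0L), all(df$retaining <= df$total))
    df$percent <- mapply(.retentionPercent, df$retaining, df$total)
    df
}

#' Two-way duplication-by-hph table of classified isolates
#'
#' The shape of the assay's event-count summary: isolates with and without
#' a chrV L duplication, split by hph status.
#'
#' @param classifications list of \linkS4class{GCRClassification} objects.
#' @return a \code{data.frame} with one row (total, withDup, withDup_hph+,
#'   withDup_hph-, withoutDup, withoutDup_hph+, withoutDup_hph-).
#' @export
duplicationByHphTable <- function(classifications) {
    dup <- vapply(classifications, function(x) x@chrVLDuplication,
                  logical(1))
    hph <- vapply(classifications, function(x) isTRUE(x@hphRetained),
                  logical(1))
    data.frame(total = length(dup),
               withDup = sum(dup),
               withDup_hphPlus = sum(dup & hph),
               withDup_hphMinus = sum(dup & !hph),
               withoutDup = sum(!dup),
               withoutDup_hphPlus = sum(!dup & hph),
               withoutDup_hphMinus = sum(!dup & !hph))
}

#' @importFrom stats aggregate
NULL
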