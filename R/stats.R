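#' @include utils.R
NULL

#' G-test of marker retention against an expected proportion
#'
#' Maximum-likelihood (log-likelihood-ratio) G-test of the observed
#' (retaining, non-retaining) counts against expected counts
#' \code{total * (p, 1-p)}: \eqn{G = 2 \sum O \ln(O/E)} with
#' \eqn{0 \ln 0 = 0}, one degree of freedom, p-value from the chi-square
#' upper tail, and no Williams correction.
#'
#' @param retaining observed retaining count.
#' @param total observed total count (>= 1).
#' @param expectedProp expected retention proportion in (0, 1), e.g. the
#'   wild-type retention frequency used as the expected distribution.
#' @return an object of class \code{htest} with the G statistic,
#'   \code{df = 1} and the p-value.
#' @examples
#' gTestRetention(18, 31, 2/27)   # p ~ 3e-13
#' @export
gTestRetention <- function(retaining, total, expectedProp) {
    if (total < 1L) stop("total must be at least 1")
    if (expectedProp <= 0 || expectedProp >= 1)
        stop("expected proportion must be strictly inside (0, 1)")
    if (retaining < 0L || retaining > total)
        stop("retaining must be in 0..total")
    O <- c(retaining, total - retaining)
    E <- total * c(expectedProp, 1 - expectedProp)
    terms <- ifelse(O > 0, O * log(O / E), 0)
    G <- 2 * sum(terms)
    p <- pchisq(G, df = 1L, lower.tail = FALSE)
    structure(list(statistic = c(G = G), parameter = c(df = 1L),
                   p.value = p,
                   method = "G-test of retention (df = 1, no Williams correction)",
                   data.name = sprintf("%d of %d vs expected %.4g",
                                       retaining, total, expectedProp)),
              class = "htest")
}

#' Two-tailed Mann-Whitney U test for rate comparisons
#'
#' Exact p-value by enumeration when the smaller sample has at most
#' \code{exactMax} values and there are no ties; otherwise the normal
#' approximation with midrank tie correction.  The assay literature infers
#' significance at p <= 0.01.
#'
#' @param a,b numeric samples (each >= 3 values).
#' @param exactMax largest min-sample size for the exact test.
#' @return list with \code{U} (for the first sample), \code{p} (two-tailed)
#'   and \code{exact}.
#' @export
mannWhitneyU <- function(a, b, exactMax = 8L) {
    if (length(a) < 3L || length(b) < 3L)
        stop("each sample must contain at least 3 values")
    ties <- any(duplicated(c(a, b)))
    exact <- !ties && min(length(a), length(b)) <= exactMax
    wt <- suppressWarnings(stats::wilcox.test(
        a, b, alternative = "two.sided", exact = exact,
        correct = !exact))
    list(U = unname(wt$statistic), p = min(1, wt$p.value), exact = exact)
}

## Lea-Coulson "method of the median": solve r/m - ln(m) = 1.24 for m.
leaCoulsonM <- function(medianCount) {
    f <- function(m) medianCount / m - log(m) - 1.24
    uniroot(f, lower = 1e-10, upper = max(10, medianCount * 10),
            tol = 1e-10)$root
}

#' Estimate a GCR rate from a fluctuation experiment
#'
#' Lea-Coulson method of the median: solves
#' \eqn{\tilde r / m - \ln m = 1.24} for the expected mutations per
#' culture m, where \eqn{\tilde r} is the median mutant count, and reports
#' \code{rate = m / cellsPerCulture}.  When the median count is 0 the
#' rate is an upper bound, computed at a median of 0.5 and flagged
#' (printed with a "<").
#'
#' @param experiment a \code{FluctuationExperiment} (list with
#'   \code{counts} and \code{cellsPerCulture}).
#' @return a list (class \code{RateEstimate}) with \code{rate},
#'   \code{isUpperBound}, \code{culturesUsed} and \code{medianCount}.
#' @export
estimateGcrRate <- function(experiment) {
    counts <- experiment$counts
    if (length(counts) == 0L) stop("no culture counts")
    if (any(counts < 0) || any(counts != floor(counts)))
        stop("mutant counts must be non-negative integers")
    cells <- experiment$cellsPerCulture
    if (is.null(cells) || cells <= 0) stop("cells per culture required")
    med <- median(counts)
    upper <- med == 0
    if (upper) med <- 0.5
    m <- leaCoulsonM(med)
    structure(list(rate = m / cells, isUpperBound = upper,
                   culturesUsed = length(counts), medianCount = median(counts)),
              class = "RateEstimate")
}

#' @export
print.RateEstimate <- function(x, ...) {
    cat(sprintf("RateEstimate: %s%.3g per cell division (%d cultures)\n",
                if (x$isUpperBound) "<" else "", x$rate, x$culturesUsed))
    invisible(x)
}

#' Format a rate estimate the way the assay tables print it
#'
#' @param x a \code{RateEstimate}.
#' @param reference optional reference rate for the parenthesised fold.
#' @return character, e.g. \code{"<6.21e-10 (0.3)"}.
#' @export
formatRate <- function(x, reference = NULL) {
    s <- sprintf("%s%.3g", if (x$isUpperBound) "<" else "", x$rate)
    if (!is.null(reference))
        s <- sprintf("%s (%.2g)", s, foldIncrease(x$rate, reference))
    s
}

#' Fold increase of a rate over a reference rate
#'
#' Ratio rounded to two significant figures, the convention of the assay
#' rate tables.
#'
#' @param rate,referenceRate positive rates.
#' @return the fold increase.
#' @examples
#' foldIncrease(4.99e-9, 2.27e-9)  # 2.2
#' @export
foldIncrease <- function(rate, referenceRate) {
    if (rate <= 0 || referenceRate <= 0)
        stop("rates must be positive")
    signif(rate / referenceRate, 2)
}
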