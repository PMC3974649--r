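#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setGeneric("chromSequence", function(x) standardGeneric("chromSequence"))
#' @rdname accessors
#' @export
setGeneric("chromFeatures", function(x) standardGeneric("chromFeatures"))
#' @rdname accessors
#' @export
setGeneric("chromLength", function(x) standardGeneric("chromLength"))
#' @rdname accessors
#' @export
setGeneric("eventClass", function(x) standardGeneric("eventClass"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("productSeq", function(x) standardGeneric("productSeq"))
#' @rdname accessors
#' @export
setGeneric("refChromosome", function(x) standardGeneric("refChromosome"))
#' @rdname accessors
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
#' @rdname accessors
#' @export
setGeneric("supportCount", function(x) standardGeneric("supportCount"))
#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))
#' @rdname accessors
#' @export
setGeneric("junctionClass", function(x) standardGeneric("junctionClass"))
#' @rdname accessors
#' @export
setGeneric("microhomologySeq", function(x) standardGeneric("microhomologySeq"))
#' @rdname accessors
#' @export
setGeneric("loopLength", function(x) standardGeneric("loopLength"))
#' @rdname accessors
#' @export
setGeneric("primingHomologyLength",
           function(x) standardGeneric("primingHomologyLength"))
#' @rdname accessors
#' @export
setGeneric("gcrClass", function(x) standardGeneric("gcrClass"))
#' @rdname accessors
#' @export
setGeneric("hphRetained", function(x) standardGeneric("hphRetained"))

#' Locate a feature interval on an assay chromosome
#'
#' @param x an \linkS4class{AssayChromosome}.
#' @param name feature name, e.g. \code{"hph"} or \code{"ura3-52"}.
#' @return a \linkS4class{GRanges} of the matching feature(s).
#' @export
setGeneric("featureRange", function(x, name) standardGeneric("featureRange"))

#' Extract the sequence of a named feature
#'
#' @param x an \linkS4class{AssayChromosome}.
#' @param name feature name.
#' @return character sequence of the (first) matching feature.
#' @export
setGeneric("featureSeq", function(x, name) standardGeneric("featureSeq"))
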