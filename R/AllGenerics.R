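#' @rdname FragmentSet-class
#' @param object,x a package object
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentSizes", function(x) standardGeneric("fragmentSizes"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentOrigins", function(x) standardGeneric("fragmentOrigins"))

#' @rdname SizeProfile-class
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname CircleCallSet-class
#' @export
setGeneric("circleCalls", function(x) standardGeneric("circleCalls"))

#' @rdname FragmentSet-class
#' @export
setMethod("fragments", "FragmentSet", function(x) x@fragments)

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentSizes", "FragmentSet",
    function(x) mcols(x@fragments)$size)

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentOrigins", "FragmentSet",
    function(x) mcols(x@fragments)$origin)

#' @rdname FragmentSet-class
#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

#' @rdname SizeProfile-class
#' @export
setMethod("profileCounts", "SizeProfile", function(x) x@counts)

#' @rdname CircleCallSet-class
#' @export
setMethod("circleCalls", "CircleCallSet", function(x) x@calls)

#' @rdname CircleCallSet-class
#' @export
setMethod("length", "CircleCallSet", function(x) length(x@calls))

setMethod("show", "FragmentSet", function(object) {
    o <- table(factor(fragmentOrigins(object), c("nuclear", "mito")))
    cat("FragmentSet with", length(object), "fragments",
        sprintf("(%d nuclear, %d mito; mito contig '%s')\n",
                o[["nuclear"]], o[["mito"]], object@mitoContig))
    if (length(object))
        cat("  size range:", paste(range(fragmentSizes(object)),
            collapse = "-"), "bp\n")
})

setMethod("show", "SizeProfile", function(object) {
    cat("SizeProfile (", object@origin, "): ", object@nTotal,
        " fragments, support 1-", length(object@counts), " bp, ",
        object@overflow, " in overflow\n", sep = "")
})

setMethod("show", "BinnedCoverage", function(object) {
    cat("BinnedCoverage:", length(object@bins), "contig(s),",
        object@binSize, "bp bins,",
        if (object@normalized) "BPM-normalized," else "raw counts,",
        object@nUsed, "fragments used\n")
})

setMethod("show", "MetaProfile", function(object) {
    cat("MetaProfile (", object@mode, "): ", object@anchorsN,
        " anchors x ", ncol(object@values), " positions\n", sep = "")
})

setMethod("show", "CircleCallSet", function(object) {
    cat("CircleCallSet with", length(object), "calls")
    if (length(object))
        cat("; total split support", sum(mcols(object@calls)$support))
    cat("\n")
})

setMethod("show", "ScenarioConfig", function(object) {
    cat("ScenarioConfig '", object@name, "': ", object@nFragments,
        " fragments, seed ", object@seed,
        ", nucleosome mode ", object@nucleosomeMode, " bp, short weight ",
        object@shortWeight, ", ", length(object@circles),
        " circle spec(s)\n", sep = "")
})

#' Mean profile across anchors
#'
#' @param x a \code{MetaProfile}
#' @return numeric vector: column means of the anchor matrix.
#' @export
meanProfile <- function(x) {
    stopifnot(is(x, "MetaProfile"))
    colMeans(x@values)
}
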