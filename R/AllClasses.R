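#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

#' FragmentSet: reconstructed cfDNA fragments
#'
#' Container for cfDNA fragments reconstructed from aligned read pairs.
#' Fragments live in a \link[GenomicRanges]{GRanges} (1-based, closed
#' intervals) whose metadata columns carry, per fragment: \code{id},
#' \code{size} (bp, from the hybrid read-length/insert-size metric),
#' \code{sizeSource} (\code{"read_length"} or \code{"insert_size"}),
#' \code{mapq} (minimum of the two mate MAPQs) and \code{origin}
#' (\code{"nuclear"} or \code{"mito"}). The \code{strand} of each range is
#' the sequencing orientation of read 1.
#'
#' @slot fragments a \code{GRanges} with the metadata columns above.
#' @slot mitoContig name of the mitochondrial contig (default "chrM");
#'   fragments on it have \code{origin == "mito"}.
#' @export
setClass("FragmentSet",
    slots = c(fragments = "GRanges", mitoContig = "character"))

.validFragmentSet <- function(object) {
    msg <- NULL
    gr <- object@fragments
    need <- c("id", "size", "sizeSource", "mapq", "origin")
    miss <- setdiff(need, colnames(mcols(gr)))
    if (length(miss))
        msg <- c(msg, paste("missing mcols:", paste(miss, collapse = ", ")))
    if (length(gr)) {
        if (any(gr@ranges@width < 1L))
            msg <- c(msg, "all fragments must have width >= 1")
        if (!is.null(mcols(gr)$size) && any(mcols(gr)$size < 1L))
            msg <- c(msg, "all sizes must be >= 1")
        if (!is.null(mcols(gr)$origin) &&
            !all(mcols(gr)$origin %in% c("nuclear", "mito")))
            msg <- c(msg, "origin must be 'nuclear' or 'mito'")
        if (!is.null(mcols(gr)$sizeSource) &&
            !all(mcols(gr)$sizeSource %in% c("read_length", "insert_size")))
            msg <- c(msg, "sizeSource must be 'read_length' or 'insert_size'")
        ins <- !is.null(mcols(gr)$sizeSource) &&
            !is.null(mcols(gr)$size)
        if (ins) {
            i <- mcols(gr)$sizeSource == "insert_size"
            if (any(mcols(gr)$size[i] != width(gr)[i]))
                msg <- c(msg,
                    "insert_size fragments must satisfy size == width")
        }
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("FragmentSet", .validFragmentSet)

#' SizeProfile: integer-binned fragment-size histogram
#'
#' Fragment-size counts over 1..\code{maxSize} bp with an overflow bin for
#' larger fragments (excluded from peak finding).
#'
#' @slot counts integer vector; \code{counts[s]} is the number of fragments
#'   of size \code{s} bp.
#' @slot origin which fragments were counted: "nuclear", "mito" or "all".
#' @slot nTotal total fragments counted (sum of counts plus overflow).
#' @slot overflow fragments larger than \code{length(counts)} bp.
#' @export
setClass("SizeProfile",
    slots = c(counts = "integer", origin = "character",
              nTotal = "integer", overflow = "integer"))

setValidity("SizeProfile", function(object) {
    if (sum(object@counts) + object@overflow != object@nTotal)
        return("sum(counts) + overflow must equal nTotal")
    if (!object@origin %in% c("nuclear", "mito", "all"))
        return("origin must be 'nuclear', 'mito' or 'all'")
    TRUE
})

#' BinnedCoverage: fragment-level binned genome coverage
#'
#' Per-contig vectors of fragment counts in fixed-width bins. Each fragment
#' increments every bin it overlaps. After \code{\link{bpmNormalize}} the
#' values are bins-per-million (BPM): bin value x 1e6 / total, so the
#' genome-wide sum is 1e6.
#'
#' @slot binSize bin width in bp (default 10).
#' @slot bins named list (one numeric vector per contig).
#' @slot normalized TRUE after BPM normalization.
#' @slot nUsed number of fragments counted (post MAPQ filter).
#' @slot seqlengths named integer vector of contig lengths.
#' @export
setClass("BinnedCoverage",
    slots = c(binSize = "integer", bins = "list", normalized = "logical",
              nUsed = "integer", seqlengths = "integer"))

#' MetaProfile: coverage matrix around anchor features
#'
#' Anchor-by-position matrix of (BPM) coverage around point anchors
#' (\code{\link{metaprofilePoint}}) or across scaled region bodies
#' (\code{\link{metaprofileScaled}}). Minus-strand anchors are
#' orientation-flipped before averaging.
#'
#' @slot values matrix, one row per usable anchor.
#' @slot positions bp offsets (point mode) or bin labels (scaled mode).
#' @slot anchorsN number of usable anchors (= nrow(values)).
#' @slot mode "point" or "scaled".
#' @export
setClass("MetaProfile",
    slots = c(values = "matrix", positions = "numeric",
              anchorsN = "integer", mode = "character"))

setValidity("MetaProfile", function(object) {
    if (nrow(object@values) != object@anchorsN)
        return("anchorsN must equal nrow(values)")
    TRUE
})

#' CircleCallSet: reconstructed circular DNA calls
#'
#' Circles reconstructed from split-read junction evidence. Each call is a
#' GRanges interval with metadata: \code{support} (junction reads),
#' \code{readIds} (comma-separated), \code{length}, and after
#' \code{\link{junctionCharacterize}} also \code{microhomologyLen} and
#' junction flank sequences.
#'
#' @slot calls GRanges of calls with the metadata columns above.
#' @export
setClass("CircleCallSet", slots = c(calls = "GRanges"))

setValidity("CircleCallSet", function(object) {
    gr <- object@calls
    if (length(gr) && any(mcols(gr)$support < 1L))
        return("all calls need support >= 1")
    TRUE
})

#' CircleSpec: planted-circle specification for the simulator
#'
#' @slot sizeClass "micro" (< 1 kb) or "long" (>= 1 kb).
#' @slot sizePeaks two-column matrix (bp, sd) of Gaussian size components;
#'   micro default rbind(c(202, 3), c(349, 3)).
#' @slot sizeWeights mixing weights of the size components.
#' @slot count number of circles to plant.
#' @slot readsPerCircle mean junction-read support per circle (Poisson).
#' @slot junctionRepeatLen planted direct-repeat length at both junction
#'   flanks (bp).
#' @export
setClass("CircleSpec",
    slots = c(sizeClass = "character", sizePeaks = "matrix",
              sizeWeights = "numeric", count = "integer",
              readsPerCircle = "numeric", junctionRepeatLen = "integer"))

setValidity("CircleSpec", function(object) {
    if (!object@sizeClass %in% c("micro", "long"))
        return("sizeClass must be 'micro' or 'long'")
    if (object@sizeClass == "micro" && any(object@sizePeaks[, 1] >= 1000))
        return("micro circle sizes must be < 1000 bp")
    if (object@sizeClass == "long" && any(object@sizePeaks[, 1] < 1000))
        return("long circle sizes must be >= 1000 bp")
    if (length(object@sizeWeights) != nrow(object@sizePeaks))
        return("one weight per size peak required")
    if (any(object@sizeWeights < 0)) return("weights must be >= 0")
    TRUE
})

#' ScenarioConfig: simulator scenario parameters
#'
#' Holds every tunable of one synthetic cfDNA scenario. The three packaged
#' scenarios emulate plasma from a healthy donor ("plasma_like"), organoid
#' culture medium in the proliferative state ("proliferative"), and in the
#' staurosporine-induced apoptotic state ("apoptotic"). See
#' \code{\link{scenarioConfig}} for the per-scenario defaults.
#'
#' @export
setClass("ScenarioConfig",
    slots = c(
        name = "character", nFragments = "integer", seed = "integer",
        nucleosomeMode = "integer", ladderPeriod = "integer",
        ladderDecay = "numeric", peakSd = "numeric",
        shortWeight = "numeric", shortMinorPeak = "integer",
        shortMinorScale = "numeric", shortKink = "integer",
        shortDecayPre = "numeric", shortDecayPost = "numeric",
        shortMin = "integer", shortMax = "integer",
        mitoFraction = "numeric", plantedEndMotif = "character",
        motifPlantProb = "numeric", repeatEndBias = "numeric",
        circles = "list", readLength = "integer",
        lowMapqFrac = "numeric", lowMapq = "integer"))

setValidity("ScenarioConfig", function(object) {
    msg <- NULL
    if (!object@name %in% c("plasma_like", "proliferative", "apoptotic"))
        msg <- c(msg, "name must be plasma_like, proliferative or apoptotic")
    if (object@shortDecayPost <= object@shortDecayPre)
        msg <- c(msg, "shortDecayPost must exceed shortDecayPre")
    w <- c(object@ladderDecay, object@shortWeight, object@mitoFraction,
           object@repeatEndBias)
    if (any(w < 0)) msg <- c(msg, "all weights must be >= 0")
    if (object@shortWeight + object@mitoFraction > 1)
        msg <- c(msg, "shortWeight + mitoFraction must be <= 1")
    if (is.null(msg)) TRUE else msg
})
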