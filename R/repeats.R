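#' Fragment terminus points
#'
#' One width-1 point per fragment terminus. The right terminus is the
#' last covered base, so containment in half-open annotation intervals is
#' well defined. Modes: \code{both} (default; each fragment contributes
#' its left and right terminus once), or a single strand-aware end
#' (\code{five_prime} is the left end of "+" fragments and the right end
#' of "-" fragments; \code{three_prime} the opposite).
#'
#' @param x a \code{\link{FragmentSet}} or GRanges.
#' @param mode which termini to emit.
#' @return GRanges of points with an \code{endType} mcol.
#' @export
endPositions <- function(x, mode = c("both", "five_prime",
                                     "three_prime")) {
    mode <- match.arg(mode)
    gr <- if (is(x, "FragmentSet")) fragments(x) else x
    if (!length(gr))
        return(.mkGRanges(character(), integer(), integer()))
    neg <- as.character(strand(gr)) == "-"
    leftP <- .mkGRanges(as.character(seqnames(gr)), start(gr), start(gr))
    rightP <- .mkGRanges(as.character(seqnames(gr)), end(gr), end(gr))
    if (mode == "both") {
        out <- c(leftP, rightP)
        mcols(out)$endType <- rep(c("left", "right"), each = length(gr))
        return(out)
    }
    wantLeft <- if (mode == "five_prime") !neg else neg
    out <- c(leftP[wantLeft], rightP[!wantLeft])
    mcols(out)$endType <- mode
    out
}

#' Annotate points with the containing repeat
#'
#' Labels each point with the repClass/repFamily/repName of the repeat
#' interval containing it, or "non-repeat". When overlapping repeats
#' contain the same point, the interval with the smaller start wins
#' (ties: the longer interval).
#'
#' @param points GRanges of width-1 points.
#' @param repeatTrack GRanges with mcols repClass, repFamily, repName.
#' @return the points with repClass/repFamily/repName mcols added.
#' @export
annotatePoints <- function(points, repeatTrack) {
    n <- length(points)
    cls <- rep("non-repeat", n); fam <- rep("non-repeat", n)
    nm <- rep("non-repeat", n)
    if (length(repeatTrack)) {
        hits <- GenomicRanges::findOverlaps(points, repeatTrack,
                                            ignore.strand = TRUE)
        if (length(hits)) {
            q <- queryHits(hits); s <- subjectHits(hits)
            # tie-break: smaller start first, then longer interval
            o <- order(q, start(repeatTrack)[s], -width(repeatTrack)[s])
            keep <- o[!duplicated(q[o])]
            q <- q[keep]; s <- s[keep]
            cls[q] <- mcols(repeatTrack)$repClass[s]
            fam[q] <- mcols(repeatTrack)$repFamily[s]
            nm[q] <- mcols(repeatTrack)$repName[s]
        }
    }
    mcols(points)$repClass <- cls
    mcols(points)$repFamily <- fam
    mcols(points)$repName <- nm
    points
}

#' Genome-expected repeat proportions
#'
#' Per repeat class, the fraction of genome bases covered by that class
#' (per-class intervals are merged before counting, so overlaps within a
#' class are not double counted).
#'
#' @param repeatTrack GRanges with a repClass mcol.
#' @param genomeBases total genome size in bp (a number) or a named
#'   seqlengths vector (summed).
#' @param by annotation level: "repClass" (default) or "repName".
#' @return named numeric vector of expected proportions.
#' @export
genomeExpected <- function(repeatTrack, genomeBases, by = "repClass") {
    G <- sum(as.numeric(genomeBases))
    labs <- unique(mcols(repeatTrack)[[by]])
    out <- vapply(labs, function(cl) {
        sum(width(GenomicRanges::reduce(
            repeatTrack[mcols(repeatTrack)[[by]] == cl]))) / G
    }, numeric(1))
    stats::setNames(out, labs)
}

#' Summarize fragment-end repeat attribution
#'
#' Observed end counts and proportions per repeat class (or subfamily),
#' with non-repeat included so proportions sum to 1 exactly.
#'
#' @param annotated GRanges from \code{\link{annotatePoints}}.
#' @param by "repClass" or "repName".
#' @param within optional repeat class; restrict the subfamily breakdown
#'   to points in that class (proportions then relative to all points).
#' @return data.table (label, n, proportion).
#' @export
summarizeRepeatEnds <- function(annotated, by = "repClass",
                                within = NULL) {
    lab <- mcols(annotated)[[by]]
    if (!is.null(within))
        lab[mcols(annotated)$repClass != within] <- "other"
    tab <- table(lab)
    data.table::data.table(label = names(tab), n = as.integer(tab),
        proportion = as.numeric(tab) / length(annotated))[
        order(-proportion)]
}

#' Compare per-replicate repeat-end proportions between fragment classes
#'
#' Welch's t test per repeat type between the NFR and NBR replicate
#' vectors. With fewer than two replicates per group no test is run and
#' the row is flagged "insufficient replicates" (proportions only).
#'
#' @param nfrProps,nbrProps matrices replicates x repeat types (matching
#'   columns).
#' @return data.table (type, meanNFR, meanNBR, t, df, p, tier, note).
#' @export
compareRepeatGroups <- function(nfrProps, nbrProps) {
    .stopIfNot(identical(colnames(nfrProps), colnames(nbrProps)),
               "repeat types must match between groups")
    rows <- lapply(colnames(nfrProps), function(ty) {
        x <- nfrProps[, ty]; y <- nbrProps[, ty]
        if (length(x) < 2 || length(y) < 2)
            return(data.table::data.table(type = ty, meanNFR = mean(x),
                meanNBR = mean(y), t = NA_real_, df = NA_real_,
                p = NA_real_, tier = NA_character_,
                note = "insufficient replicates"))
        w <- welchT(x, y)
        data.table::data.table(type = ty, meanNFR = mean(x),
            meanNBR = mean(y), t = w$t, df = w$df, p = w$p,
            tier = w$tier, note = "")
    })
    data.table::rbindlist(rows)
}
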