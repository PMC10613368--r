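#' Hybrid fragment-size metric
#'
#' Fragment size from a concordant read pair: the original read length for
#' fragments shorter than the sequencing read length (overlap-trimmed mates
#' carry the full fragment), the absolute insert size (TLEN) otherwise.
#' Read-1 length drives the branch; for sub-read-length fragments both
#' mates have identical length under overlap trimming, so the choice is
#' immaterial there.
#'
#' @param read1Len length of the read-1 sequence (bp).
#' @param tlen SAM template length of read 1 (signed).
#' @param readLength platform read length (default 150).
#' @return list(size, source) with source "read_length" or "insert_size",
#'   or \code{NULL} when the size is unknowable (full-length read with
#'   TLEN 0).
#' @export
hybridSize <- function(read1Len, tlen, readLength = 150L) {
    if (read1Len < readLength)
        return(list(size = as.integer(read1Len), source = "read_length"))
    if (tlen == 0L) return(NULL)
    list(size = as.integer(abs(tlen)), source = "insert_size")
}

#' Fragment-size histogram
#'
#' Integer histogram of fragment sizes over 1..\code{maxSize} bp, split by
#' origin (nuclear vs mitochondrial). Fragments above \code{maxSize} are
#' counted in an overflow bin and excluded from peak analysis.
#'
#' @param x a \code{\link{FragmentSet}}.
#' @param origin "nuclear", "mito" or "all".
#' @param maxSize histogram support cap (bp).
#' @return a \code{\link{SizeProfile}}.
#' @export
sizeHistogram <- function(x, origin = c("all", "nuclear", "mito"),
                          maxSize = 1000L) {
    origin <- match.arg(origin)
    sz <- fragmentSizes(x)
    if (origin != "all") sz <- sz[fragmentOrigins(x) == origin]
    counts <- tabulate(sz[sz <= maxSize], nbins = maxSize)
    new("SizeProfile", counts = as.integer(counts), origin = origin,
        nTotal = length(sz), overflow = sum(sz > maxSize))
}

# local maxima with prominence on a numeric vector; plateaus report
# their center; returns positions (indices into x) ordered by height
# descending (ties: leftmost first)
.peaksWithProminence <- function(x, minProm) {
    r <- rle(x)
    nr <- length(r$values)
    if (nr < 3L) return(integer())
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    v <- r$values
    cand <- which(seq_len(nr) > 1L & seq_len(nr) < nr &
                  v > c(Inf, v[-nr]) & v > c(v[-1L], Inf))
    if (!length(cand)) return(integer())
    prom <- vapply(cand, function(j) {
        h <- v[j]
        hl <- which(v[seq_len(j - 1L)] > h)
        lvalley <- if (length(hl)) v[(max(hl) + 1L):(j - 1L)]
                   else v[seq_len(j - 1L)]
        hr <- which(v[(j + 1L):nr] > h)
        rvalley <- if (length(hr)) v[j + seq_len(min(hr) - 1L)]
                   else v[(j + 1L):nr]
        h - max(min(c(lvalley, h)), min(c(rvalley, h)))
    }, numeric(1))
    keep <- cand[prom >= minProm]
    pos <- (starts[keep] + ends[keep]) %/% 2L
    pos[order(x[pos], -pos, decreasing = TRUE)]
}

#' Find peaks in a size histogram
#'
#' Local maxima of the moving-average-smoothed histogram within
#' \code{[lo, hi]} whose prominence is at least
#' \code{minProminenceFrac} times the global maximum of the smoothed
#' histogram in that range, sorted by height descending.
#'
#' @param profile a \code{\link{SizeProfile}} (or bare count vector
#'   indexed by size).
#' @param lo,hi size range searched (bp), \code{hi > lo}.
#' @param smoothWindow centered moving-average window (bp).
#' @param minProminenceFrac prominence floor as a fraction of the range
#'   maximum.
#' @param minDistance minimum separation between reported peaks (bp);
#'   among closer candidates only the tallest survives. Must stay below
#'   the 10 bp ladder period so nucleosomal comb peaks remain separable.
#' @return integer vector of peak sizes (bp), tallest first; empty when
#'   nothing qualifies.
#' @export
findSizePeaks <- function(profile, lo, hi, smoothWindow = 5L,
                          minProminenceFrac = 0.05, minDistance = 5L) {
    .stopIfNot(hi > lo, "hi must exceed lo")
    counts <- if (is(profile, "SizeProfile")) profileCounts(profile)
              else profile
    hi <- min(hi, length(counts))
    if (lo >= hi) return(integer())
    sm <- .movingAverage(counts, smoothWindow)
    seg <- sm[lo:hi]
    if (max(seg) <= 0) return(integer())
    idx <- .peaksWithProminence(seg, minProminenceFrac * max(seg))
    # greedy tall-first selection with a minimum peak separation
    sel <- integer(0)
    for (i in idx)
        if (!length(sel) || all(abs(sel - i) >= minDistance))
            sel <- c(sel, i)
    as.integer(sel + lo - 1L)
}

#' Estimate sub-modal size periodicity
#'
#' Detrends the histogram within \code{window} by subtracting a 21 bp
#' centered moving average and returns the autocorrelation-argmax lag
#' within \code{lagRange}. Returns \code{NULL} (no periodicity) when the
#' maximum autocorrelation falls below \code{minAutocorr}; the default
#' floor 0.4 sits above the 99th percentile of the null (aperiodic)
#' distribution of this statistic, while genuine 10 bp nucleosomal combs
#' score around 0.6.
#'
#' @param profile a \code{\link{SizeProfile}} or count vector.
#' @param window size window analyzed, default c(100, 160) bp.
#' @param lagRange candidate periods in bp, default c(6, 15).
#' @param minAutocorr detection floor on the peak autocorrelation.
#' @return period in bp, or \code{NULL}.
#' @export
estimatePeriodicity <- function(profile, window = c(100L, 160L),
                                lagRange = c(6L, 15L), minAutocorr = 0.4) {
    counts <- if (is(profile, "SizeProfile")) profileCounts(profile)
              else profile
    .stopIfNot(window[2] <= length(counts),
               "window must lie within the profile support")
    s <- window[1]:window[2]
    x <- counts[s] - .movingAverage(counts, 21L)[s]
    x <- x - mean(x)
    denom <- sum(x^2)
    if (denom == 0) return(NULL)
    lags <- lagRange[1]:lagRange[2]
    n <- length(x)
    r <- vapply(lags, function(k)
        sum(x[seq_len(n - k)] * x[(k + 1L):n]) / denom, numeric(1))
    if (max(r) < minAutocorr) return(NULL)
    as.integer(lags[which.max(r)])
}

#' Detect the short-fragment slope-change threshold
#'
#' Locates the size at which the log-scale size distribution changes slope
#' (the boundary between nucleosome-free and nucleosome-bound fragments).
#' A continuous two-segment linear model is fitted to
#' \code{log10(count + 1)} against size by exhaustive breakpoint search;
#' the SSE-minimizing breakpoint is returned with a fit-quality score
#' \code{1 - SSE_2seg / SSE_1seg}.
#'
#' The fit operates on the trailing running-minimum envelope of the
#' histogram (window \code{envWindow}, spanning one full 10 bp nucleosomal
#' period): the envelope tracks the sub-nucleosomal baseline between the
#' ladder peaks, so the breakpoint reflects the short-fragment component
#' rather than the nucleosomal comb.
#'
#' @param profile a \code{\link{SizeProfile}} or count vector.
#' @param lo,hi fitting range (bp), default 60-160.
#' @param envWindow trailing minimum-filter window (bp).
#' @param minSupport minimum distinct sizes with nonzero counts required
#'   in \code{[lo, hi]}.
#' @return list(threshold, quality) or \code{NULL} (with a warning) on
#'   insufficient support. A quality below ~0.2 indicates no real slope
#'   change.
#' @export
detectSlopeChange <- function(profile, lo = 60L, hi = 160L,
                              envWindow = 11L, minSupport = 20L) {
    counts <- if (is(profile, "SizeProfile")) profileCounts(profile)
              else profile
    hi <- min(hi, length(counts))
    s <- lo:hi
    if (sum(counts[s] > 0) < minSupport) {
        warning("fewer than ", minSupport,
                " sizes with nonzero counts in [", lo, ",", hi, "]")
        return(NULL)
    }
    env <- vapply(s, function(p) min(counts[max(1L, p - envWindow + 1L):p]),
                  numeric(1))
    y <- log10(env + 1)
    best <- NA_integer_; bestSSE <- Inf
    for (b in (lo + 5L):(hi - 5L)) {
        X <- cbind(1, s, pmax(0, s - b))
        sse <- sum(stats::.lm.fit(X, y)$residuals^2)
        if (sse < bestSSE) { bestSSE <- sse; best <- b }
    }
    sse1 <- sum(stats::.lm.fit(cbind(1, s), y)$residuals^2)
    list(threshold = as.integer(best),
         quality = if (sse1 > 0) 1 - bestSSE / sse1 else 0)
}

#' Partition fragments into NFR and NBR classes
#'
#' Nucleosome-free-region (NFR) fragments are those with size at or below
#' the threshold; nucleosome-bound-region (NBR) fragments are larger. The
#' partition is exhaustive and exclusive.
#'
#' @param x a \code{\link{FragmentSet}}.
#' @param threshold size cutoff in bp (default 118).
#' @return list with \code{threshold}, \code{nfr} and \code{nbr}
#'   (\code{FragmentSet}s) and the id vectors \code{nfrIds}, \code{nbrIds}.
#' @export
classifyFragments <- function(x, threshold = 118L) {
    sz <- fragmentSizes(x)
    isNfr <- sz <= threshold
    gr <- fragments(x)
    list(threshold = as.integer(threshold),
         nfr = methods::initialize(x, fragments = gr[isNfr]),
         nbr = methods::initialize(x, fragments = gr[!isNfr]),
         nfrIds = mcols(gr)$id[isNfr],
         nbrIds = mcols(gr)$id[!isNfr])
}

#' Write a size profile as TSV (size, count, origin)
#' @param profile a \code{\link{SizeProfile}}.
#' @param path output path.
#' @export
writeSizeProfile <- function(profile, path) {
    data.table::fwrite(data.table::data.table(
        size = seq_along(profile@counts), count = profile@counts,
        origin = profile@origin), path, sep = "\t")
    invisible(path)
}
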