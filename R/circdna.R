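# leading soft-clip length of a CIGAR (reference-oriented)
.leadingClip <- function(cigar) {
    out <- integer(length(cigar))
    hit <- grepl("^[0-9]+S", cigar)
    out[hit] <- as.integer(sub("S.*", "",
        regmatches(cigar, regexpr("^[0-9]+S", cigar))))
    out
}

#' Collect circular-DNA junction evidence from split alignments
#'
#' A read supports a circle junction when it has exactly one primary and
#' one supplementary alignment on the same contig and strand, and the
#' query places the genomically-downstream segment before the upstream
#' one (circle end ligated to circle start). Breakpoints come from the
#' CIGAR-implied reference extents: the evidence interval is
#' [upstream segment start, downstream segment end]. Reads not matching
#' the pattern are ignored; a primary lacking a parseable SA tag is
#' skipped with a warning.
#'
#' @param aln alignment table from \code{\link{readAlignments}}.
#' @return data.table (readId, contig, leftBreak, rightBreak) with
#'   1-based closed breakpoint coordinates.
#' @export
collectJunctions <- function(aln) {
    empty <- data.table::data.table(readId = character(),
        contig = character(), leftBreak = integer(),
        rightBreak = integer())
    withSupp <- aln[aln$qname %in% aln$qname[aln$isSupplementary], ]
    if (nrow(withSupp) == 0L) return(empty)
    cnt <- table(withSupp$qname)
    keepQ <- names(cnt)[cnt == 2L]
    withSupp <- withSupp[withSupp$qname %in% keepQ, ]
    if (nrow(withSupp) == 0L) return(empty)
    data.table::setorder(withSupp, qname, isSupplementary)
    prim <- withSupp[!withSupp$isSupplementary, ]
    supp <- withSupp[withSupp$isSupplementary, ]
    common <- intersect(prim$qname, supp$qname)
    prim <- prim[match(common, prim$qname), ]
    supp <- supp[match(common, supp$qname), ]
    badSA <- is.na(prim$sa) | !nzchar(prim$sa)
    if (any(badSA))
        warning(sum(badSA), " split read(s) with missing/malformed SA ",
                "tag skipped")
    ok <- !badSA & prim$contig == supp$contig &
        prim$isReverse == supp$isReverse
    prim <- prim[ok, ]; supp <- supp[ok, ]
    if (nrow(prim) == 0L) return(empty)
    pStart <- prim$pos; pEnd <- prim$pos + .cigarRefWidth(prim$cigar) - 1L
    sStart <- supp$pos; sEnd <- supp$pos + .cigarRefWidth(supp$cigar) - 1L
    pClip <- .leadingClip(prim$cigar); sClip <- .leadingClip(supp$cigar)
    # reference-oriented query order: smaller leading clip comes first
    firstIsPrim <- pClip < sClip
    fStart <- ifelse(firstIsPrim, pStart, sStart)
    fEnd <- ifelse(firstIsPrim, pEnd, sEnd)
    gStart <- ifelse(firstIsPrim, sStart, pStart)
    gEnd <- ifelse(firstIsPrim, sEnd, pEnd)
    # circle junction: downstream segment first in the query
    isJunction <- fStart > gEnd
    data.table::data.table(readId = prim$qname[isJunction],
        contig = prim$contig[isJunction],
        leftBreak = as.integer(gStart[isJunction]),
        rightBreak = as.integer(fEnd[isJunction]))
}

#' Cluster junction evidence into circle calls
#'
#' Single-linkage clustering of evidence whose breakpoints both agree
#' within \code{tol} bp; call coordinates are the per-cluster median
#' breakpoints and calls with fewer than \code{minSupport} supporting
#' reads are dropped.
#'
#' @param evidence data.table from \code{\link{collectJunctions}}.
#' @param tol breakpoint agreement tolerance (bp).
#' @param minSupport minimum split-read support per call.
#' @return a \code{\link{CircleCallSet}}.
#' @export
clusterCircleCalls <- function(evidence, tol = 5L, minSupport = 2L) {
    if (nrow(evidence) == 0L)
        return(new("CircleCallSet",
                   calls = .mkGRanges(character(), integer(), integer())))
    rows <- list()
    for (ct in unique(evidence$contig)) {
        ev <- evidence[evidence$contig == ct, ]
        data.table::setorder(ev, leftBreak, rightBreak)
        n <- nrow(ev)
        parent <- seq_len(n)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        for (i in seq_len(n)) {
            j <- i + 1L
            while (j <= n && ev$leftBreak[j] - ev$leftBreak[i] <= tol) {
                if (abs(ev$rightBreak[j] - ev$rightBreak[i]) <= tol) {
                    ri <- find(i); rj <- find(j)
                    if (ri != rj) parent[rj] <- ri
                }
                j <- j + 1L
            }
        }
        root <- vapply(seq_len(n), find, integer(1))
        for (r in unique(root)) {
            m <- root == r
            if (sum(m) < minSupport) next
            rows[[length(rows) + 1L]] <- data.table::data.table(
                contig = ct,
                start = as.integer(round(stats::median(ev$leftBreak[m]))),
                end = as.integer(round(stats::median(ev$rightBreak[m]))),
                support = sum(m),
                readIds = paste(ev$readId[m], collapse = ","))
        }
    }
    if (!length(rows))
        return(new("CircleCallSet",
                   calls = .mkGRanges(character(), integer(), integer())))
    dt <- data.table::rbindlist(rows)
    gr <- .mkGRanges(dt$contig, dt$start, dt$end)
    mcols(gr) <- DataFrame(support = dt$support, readIds = dt$readIds,
                           length = width(gr))
    new("CircleCallSet", calls = sort(gr))
}

#' Remove calls overlapping tandem-duplication regions
#'
#' Tandem-duplication read-through junctions are indistinguishable from
#' circle junctions, so calls overlapping a known duplication interval by
#' at least 1 bp are excluded.
#'
#' @param x a \code{\link{CircleCallSet}}.
#' @param dupTrack GRanges of tandem-duplication intervals.
#' @return filtered \code{CircleCallSet}; removals are messaged.
#' @export
filterTandemDuplications <- function(x, dupTrack) {
    gr <- circleCalls(x)
    hit <- IRanges::overlapsAny(gr, dupTrack, ignore.strand = TRUE)
    message(sum(hit), " call(s) removed by tandem-duplication overlap")
    methods::initialize(x, calls = gr[!hit])
}

#' Circle length spectrum
#'
#' Cumulative length distribution over a log-spaced grid, the sub-1 kb
#' integer length histogram, its peaks, and (when detectable) its 10 bp
#' oscillation period; the size-profile peak and periodicity detectors
#' are reused so one implementation serves both fragments and circles.
#'
#' @param x a \code{\link{CircleCallSet}}.
#' @param weight "per_call" (default; each call once) or "per_read"
#'   (calls weighted by split support).
#' @param microMax microDNA cutoff (default 1000 bp).
#' @param peakRange size range searched for peaks within the sub-cutoff
#'   histogram.
#' @return list: lengths, cumulative (data.table length/proportion),
#'   histogram (counts indexed by bp), peaks, period (or NULL),
#'   propUnderCutoff.
#' @export
lengthSpectrum <- function(x, weight = c("per_call", "per_read"),
                           microMax = 1000L, peakRange = c(100L, 999L)) {
    weight <- match.arg(weight)
    gr <- circleCalls(x)
    .stopIfNot(length(gr) >= 1, "no calls")
    len <- width(gr)
    if (weight == "per_read") len <- rep(len, mcols(gr)$support)
    grid <- unique(as.integer(round(10^seq(log10(max(min(len), 1)),
                                           log10(max(len)),
                                           length.out = 200L))))
    cum <- data.table::data.table(length = grid,
        proportion = vapply(grid, function(g) mean(len <= g), numeric(1)))
    counts <- tabulate(len[len < microMax], nbins = microMax - 1L)
    peaks <- findSizePeaks(counts, peakRange[1], peakRange[2])
    period <- if (sum(counts) > 0)
        estimatePeriodicity(counts,
            window = c(max(100L, peakRange[1]),
                       min(length(counts), 400L)))
    else NULL
    list(lengths = len, cumulative = cum, histogram = counts,
         peaks = peaks, period = period,
         propUnderCutoff = mean(len < microMax))
}

#' Characterize circle junctions
#'
#' Extracts \code{w} reference bases on each side of both breakpoints
#' (PFMs for the start-side and end-side junction flanks), measures the
#' junction microhomology (longest exact prefix match between the
#' sequence starting at the circle start and the sequence starting just
#' past the circle end: the direct-repeat length), and attributes
#' breakpoint positions to repeat classes, split by the microDNA cutoff.
#'
#' @param x a \code{\link{CircleCallSet}}.
#' @param reference reference list with the genome.
#' @param w flank width (bp, default 10).
#' @param repeatTrack GRanges repeat annotation (optional).
#' @param microMax size cutoff splitting the repeat attribution.
#' @param maxMH maximum microhomology length measured.
#' @return list: startFlankPFM, endFlankPFM, microhomology (per call),
#'   repeatProps (data.table with sizeGroup), calls (with
#'   microhomologyLen and flank sequences in mcols).
#' @export
junctionCharacterize <- function(x, reference, w = 10L,
                                 repeatTrack = NULL, microMax = 1000L,
                                 maxMH = 25L) {
    gr <- circleCalls(x)
    .stopIfNot(length(gr) >= 1, "no calls")
    ct <- as.character(seqnames(gr))
    s <- start(gr); e <- end(gr)
    startFlank <- character(length(gr)); endFlank <- character(length(gr))
    mh <- integer(length(gr))
    for (c1 in unique(ct)) {
        i <- which(ct == c1)
        chrSeq <- reference$genome[[c1]]
        startFlank[i] <- .paddedSlice(chrSeq, s[i] - w, s[i] + w - 1L)
        endFlank[i] <- .paddedSlice(chrSeq, e[i] - w + 1L, e[i] + w)
        sRun <- .paddedSlice(chrSeq, s[i], s[i] + maxMH - 1L)
        eRun <- .paddedSlice(chrSeq, e[i] + 1L, e[i] + maxMH)
        mh[i] <- vapply(seq_along(i), function(k) {
            a <- strsplit(sRun[k], "")[[1]]; b <- strsplit(eRun[k], "")[[1]]
            neq <- which(a != b | a == "N")
            if (length(neq)) neq[1] - 1L else maxMH
        }, integer(1))
    }
    mcols(gr)$microhomologyLen <- mh
    mcols(gr)$startFlank <- startFlank
    mcols(gr)$endFlank <- endFlank
    repeatProps <- NULL
    if (!is.null(repeatTrack)) {
        pts <- c(.mkGRanges(ct, s, s), .mkGRanges(ct, e, e))
        grp <- rep(ifelse(width(gr) < microMax, "micro", "large"), 2)
        ann <- annotatePoints(pts, repeatTrack)
        rows <- lapply(unique(grp), function(g) {
            sm <- summarizeRepeatEnds(ann[grp == g])
            sm$sizeGroup <- g
            sm
        })
        repeatProps <- data.table::rbindlist(rows)
    }
    list(startFlankPFM = buildPFM(startFlank),
         endFlankPFM = buildPFM(endFlank),
         microhomology = mh, repeatProps = repeatProps,
         calls = methods::initialize(x, calls = gr))
}

#' Circle abundance in supporting reads per million mapped
#'
#' CPM = total split support x 1e6 / mapped reads, reported overall and
#' split at the microDNA cutoff. Invariant to sequencing depth at fixed
#' circle content.
#'
#' @param x a \code{\link{CircleCallSet}}.
#' @param nMappedReads total mapped reads in the library.
#' @param microMax size cutoff (default 1000 bp).
#' @return list(overall, micro, large).
#' @export
circleCPM <- function(x, nMappedReads, microMax = 1000L) {
    .stopIfNot(nMappedReads > 0, "nMappedReads must be positive")
    gr <- circleCalls(x)
    supp <- if (length(gr)) mcols(gr)$support else integer()
    isMicro <- if (length(gr)) width(gr) < microMax else logical()
    list(overall = sum(supp) * 1e6 / nMappedReads,
         micro = sum(supp[isMicro]) * 1e6 / nMappedReads,
         large = sum(supp[!isMicro]) * 1e6 / nMappedReads)
}
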