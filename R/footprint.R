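#' Fragment-level binned genome coverage
#'
#' Counts, per fixed-width bin, the fragments overlapping it: each
#' fragment increments every bin it touches, once (fragments, not reads,
#' carry the protection signal). Fragments with MAPQ below \code{mapqMin}
#' contribute nothing.
#'
#' @param x a \code{\link{FragmentSet}} (its GRanges must carry
#'   seqlengths).
#' @param binSize bin width in bp (default 10).
#' @param mapqMin minimum fragment MAPQ used (default 30).
#' @return a \code{\link{BinnedCoverage}} of raw counts.
#' @export
binnedCoverage <- function(x, binSize = 10L, mapqMin = 30L) {
    gr <- fragments(x)
    sl <- GenomeInfoDb::seqlengths(gr)
    .stopIfNot(!any(is.na(sl)), "fragments must carry seqlengths")
    gr <- gr[mcols(gr)$mapq >= mapqMin]
    bins <- lapply(names(sl), function(ct) {
        nb <- as.integer(ceiling(sl[[ct]] / binSize))
        g <- gr[as.character(seqnames(gr)) == ct]
        if (!length(g)) return(numeric(nb))
        b0 <- (start(g) - 1L) %/% binSize + 1L
        b1 <- (end(g) - 1L) %/% binSize + 1L
        idx <- sequence(b1 - b0 + 1L, from = b0)
        as.numeric(tabulate(idx, nbins = nb))
    })
    new("BinnedCoverage", binSize = as.integer(binSize),
        bins = stats::setNames(bins, names(sl)), normalized = FALSE,
        nUsed = length(gr), seqlengths = stats::setNames(as.integer(sl),
                                                         names(sl)))
}

#' BPM-normalize binned coverage
#'
#' Bins per million: each bin becomes \code{count * 1e6 / total}, so the
#' genome-wide sum is 1e6 (the TPM analogue for sequencing depth). Scale
#' invariant: doubling all raw counts leaves BPM unchanged.
#'
#' @param cov a raw \code{\link{BinnedCoverage}}.
#' @return the normalized \code{BinnedCoverage}.
#' @export
bpmNormalize <- function(cov) {
    total <- sum(vapply(cov@bins, sum, numeric(1)))
    .stopIfNot(total > 0, "cannot BPM-normalize all-zero coverage")
    methods::initialize(cov,
        bins = lapply(cov@bins, function(v) v * 1e6 / total),
        normalized = TRUE)
}

# matrix of bin values sampled at genome coordinates; rows = anchors
.sampleBins <- function(cov, contig, positions) {
    # positions: matrix anchors x k of genome coordinates (1-based)
    binIdx <- (positions - 1L) %/% cov@binSize + 1L
    out <- matrix(NA_real_, nrow(positions), ncol(positions))
    for (ct in unique(contig)) {
        i <- contig == ct
        out[i, ] <- cov@bins[[ct]][binIdx[i, , drop = FALSE]]
    }
    out
}

#' Meta-profile around point anchors
#'
#' Extracts coverage at bin resolution in a window of \code{flank} bp on
#' each side of every anchor point; minus-strand anchors are reversed
#' before averaging, so profiles are in the anchor's own 5' to 3'
#' orientation. Out-of-bounds anchors are dropped with a message.
#'
#' @param cov a (typically BPM-normalized) \code{\link{BinnedCoverage}}.
#' @param anchors GRanges of anchor points (starts are used) with strand.
#' @param flank half-window in bp (default 1000).
#' @return a \code{\link{MetaProfile}} (mode "point"); positions are bin
#'   center offsets in bp.
#' @export
metaprofilePoint <- function(cov, anchors, flank = 1000L) {
    bs <- cov@binSize
    nb <- as.integer(2L * flank / bs)
    ct <- as.character(seqnames(anchors))
    p <- start(anchors)
    sl <- cov@seqlengths[ct]
    ok <- p - flank >= 1L & p + flank <= sl
    if (any(!ok)) message(sum(!ok), " out-of-bounds anchor(s) dropped")
    .stopIfNot(any(ok), "no usable anchors")
    anchors <- anchors[ok]; ct <- ct[ok]; p <- p[ok]
    offsets <- seq(-flank, flank - bs, by = bs)
    posMat <- outer(p, offsets + 1L, `+`)   # left edge of each sampled bin
    vals <- .sampleBins(cov, ct, posMat)
    neg <- as.character(strand(anchors)) == "-"
    vals[neg, ] <- vals[neg, ncol(vals):1, drop = FALSE]
    new("MetaProfile", values = vals,
        positions = as.numeric(offsets + bs / 2),
        anchorsN = length(p), mode = "point")
}

#' Meta-profile across scaled region bodies
#'
#' Resamples each region body to \code{bodyBins} positions by linear
#' interpolation of its bin values and appends unscaled flanks; rows of
#' minus-strand regions are flipped. Regions shorter than one bin are
#' dropped with a warning.
#'
#' @param cov a \code{\link{BinnedCoverage}}.
#' @param regions GRanges of regions with strand.
#' @param bodyBins number of positions the body is scaled to.
#' @param flank unscaled flank in bp on each side.
#' @return a \code{\link{MetaProfile}} (mode "scaled"); positions are flank
#'   offsets in bp and body bin indices 1..bodyBins in between.
#' @export
metaprofileScaled <- function(cov, regions, bodyBins = 100L,
                              flank = 1000L) {
    bs <- cov@binSize
    nf <- as.integer(flank / bs)
    ct <- as.character(seqnames(regions))
    sl <- cov@seqlengths[ct]
    tooShort <- width(regions) < bs
    if (any(tooShort))
        warning(sum(tooShort), " region(s) shorter than one bin dropped")
    ok <- !tooShort & start(regions) - flank >= 1L &
        end(regions) + flank <= sl
    .stopIfNot(any(ok), "no usable regions")
    regions <- regions[ok]; ct <- ct[ok]
    rows <- lapply(seq_along(regions), function(i) {
        v <- cov@bins[[ct[i]]]
        s <- start(regions)[i]; e <- end(regions)[i]
        b0 <- (s - 1L) %/% bs + 1L; b1 <- (e - 1L) %/% bs + 1L
        body <- v[b0:b1]
        body <- if (length(body) == 1L) rep(body, bodyBins)
            else stats::approx(seq_along(body), body,
                xout = seq(1, length(body), length.out = bodyBins))$y
        lf <- v[((s - flank - 1L) %/% bs + 1L):(b0 - 1L)][seq_len(nf)]
        rf <- v[(b1 + 1L):((e + flank - 1L) %/% bs + 1L)][seq_len(nf)]
        row <- c(lf, body, rf)
        if (as.character(strand(regions))[i] == "-") rev(row) else row
    })
    vals <- do.call(rbind, rows)
    new("MetaProfile", values = vals,
        positions = c(seq(-flank, -bs, by = bs),
                      seq_len(bodyBins),
                      bodyBins + seq_len(nf) * bs),
        anchorsN = length(regions), mode = "scaled")
}

#' Sample-by-region matrix of mean BPM
#'
#' One row per sample, one column per region; entries are the mean BPM
#' over the bins each region covers. Invariant to library-size rescaling
#' (inputs are BPM). Zero-variance columns are flagged in the
#' \code{"zeroVariance"} attribute.
#'
#' @param covs named list of BPM-normalized \code{\link{BinnedCoverage}},
#'   one per sample, over the same genome.
#' @param regions GRanges of regions (shared across samples).
#' @return numeric matrix samples x regions.
#' @export
regionMatrix <- function(covs, regions) {
    .stopIfNot(length(covs) >= 2, "at least two samples are required")
    sls <- lapply(covs, function(cv) cv@seqlengths)
    if (!all(vapply(sls[-1], identical, logical(1), sls[[1]])))
        stop("samples cover different genomes")
    ct <- as.character(seqnames(regions))
    rows <- t(vapply(covs, function(cv) {
        bs <- cv@binSize
        vapply(seq_along(regions), function(i) {
            b0 <- (start(regions)[i] - 1L) %/% bs + 1L
            b1 <- (end(regions)[i] - 1L) %/% bs + 1L
            mean(cv@bins[[ct[i]]][b0:b1])
        }, numeric(1))
    }, numeric(length(regions))))
    rownames(rows) <- names(covs)
    colnames(rows) <- if (!is.null(mcols(regions)$name))
        mcols(regions)$name else paste0("region", seq_along(regions))
    zv <- apply(rows, 2, stats::var) == 0
    attr(rows, "zeroVariance") <- which(zv)
    rows
}

#' Write binned coverage as bedGraph
#' @param cov a \code{\link{BinnedCoverage}}.
#' @param path output path.
#' @export
writeBedGraph <- function(cov, path) {
    dts <- lapply(names(cov@bins), function(ct) {
        v <- cov@bins[[ct]]
        nb <- length(v)
        data.table::data.table(ct,
            start = (seq_len(nb) - 1L) * cov@binSize,
            end = pmin(seq_len(nb) * cov@binSize, cov@seqlengths[[ct]]),
            value = v)
    })
    data.table::fwrite(data.table::rbindlist(dts), path, sep = "\t",
                       col.names = FALSE)
    invisible(path)
}
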