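#' Plant circular DNA on a synthetic reference
#'
#' Each circle is an interval on the nuclear contig, placed to avoid the
#' blacklist and tandem-duplication tracks. Before "excision", the
#' reference receives a planted direct repeat: the
#' \code{junctionRepeatLen} bases at the circle start are copied to the
#' position immediately after the circle end, giving the junction the
#' direct-repeat (microhomology) context characteristic of microDNA.
#' Junction reads are sampled across the circle origin: mapped to the
#' linear reference, each read splits into the 3' portion of the circle
#' followed by its 5' portion.
#'
#' @param specs list of \code{\link{circleSpec}} objects.
#' @param reference result of \code{\link{buildReference}}; its genome is
#'   modified (direct-repeat planting) and returned.
#' @param seed RNG seed.
#' @param readLength junction read length (bp).
#' @return list with \code{circles} (GRanges with mcols circleId, size,
#'   sizeClass, junctionReadIds comma-separated), \code{junctions}
#'   (data.table of per-read split geometry), and the modified
#'   \code{reference}.
#' @export
plantCircles <- function(specs, reference, seed = 1L, readLength = 150L) {
    set.seed(seed)
    contigs <- names(reference$seqlengths)
    nucContig <- setdiff(contigs, reference$mitoContig)[1]
    nucLen <- reference$seqlengths[[nucContig]]
    avoid <- c(reference$tracks$blacklist, reference$tracks$tandem_dups)
    margin <- 500L
    occupied <- logical(nucLen)
    occupied[unlist(Map(seq.int, pmax(start(avoid), 1L),
                        pmin(end(avoid), nucLen)))] <- TRUE
    circRows <- list(); juncRows <- list()
    cid <- 0L
    genome <- reference$genome
    for (spec in specs) {
        for (i in seq_len(spec@count)) {
            cid <- cid + 1L
            pk <- sample(nrow(spec@sizePeaks), 1L, prob = spec@sizeWeights)
            L <- max(50L, as.integer(round(stats::rnorm(1,
                spec@sizePeaks[pk, 1], spec@sizePeaks[pk, 2]))))
            .stopIfNot(L + 2L * margin < nucLen,
                       "circle larger than the contig")
            s <- .placeInterval(occupied, L + spec@junctionRepeatLen,
                                margin, maxTry = 500L)
            if (is.na(s)) stop("could not place circle ", cid,
                               " outside masked regions")
            occupied[s:(s + L + spec@junctionRepeatLen - 1L)] <- TRUE
            e <- s + L - 1L
            jl <- spec@junctionRepeatLen
            if (jl > 0L)  # direct repeat: start-flank bases copied past end
                subseq(genome[[nucContig]], e + 1L, e + jl) <-
                    subseq(genome[[nucContig]], s, s + jl - 1L)
            nReads <- stats::rpois(1L, spec@readsPerCircle)
            rid <- character(0)
            if (nReads > 0L) {
                minSeg <- 20L
                rl <- min(readLength, L - minSeg)
                .stopIfNot(rl >= 2L * minSeg,
                           "circle too small to carry split junction reads")
                lenA <- sample(minSeg:(rl - minSeg), nReads, replace = TRUE)
                lenB <- rl - lenA
                rid <- sprintf("J%05d_%02d", cid, seq_len(nReads))
                juncRows[[length(juncRows) + 1L]] <- data.table::data.table(
                    readId = rid, circleId = cid, contig = nucContig,
                    circleStart = s, circleEnd = e, lenA = lenA,
                    lenB = lenB,
                    orientation = sample(c("+", "-"), nReads,
                                         replace = TRUE))
            }
            circRows[[length(circRows) + 1L]] <- data.table::data.table(
                circleId = cid, contig = nucContig, start = s, end = e,
                size = L, sizeClass = spec@sizeClass,
                junctionReadIds = paste(rid, collapse = ","))
        }
    }
    reference$genome <- genome
    circ <- data.table::rbindlist(circRows)
    junc <- if (length(juncRows)) data.table::rbindlist(juncRows)
            else data.table::data.table(readId = character(),
                circleId = integer(), contig = character(),
                circleStart = integer(), circleEnd = integer(),
                lenA = integer(), lenB = integer(),
                orientation = character())
    gr <- if (nrow(circ)) {
        g <- .mkGRanges(circ$contig, circ$start, circ$end,
                        seqlengths = reference$seqlengths)
        mcols(g) <- DataFrame(circleId = circ$circleId, size = circ$size,
            sizeClass = circ$sizeClass,
            junctionReadIds = circ$junctionReadIds)
        g
    } else .mkGRanges(character(), integer(), integer(),
                      seqlengths = reference$seqlengths)
    list(circles = gr, junctions = junc, reference = reference)
}
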