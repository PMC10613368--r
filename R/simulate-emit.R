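# sequence extraction helper: character vector of genome slices
.refSlices <- function(genome, contig, start, end) {
    out <- character(length(start))
    for (ct in unique(contig)) {
        i <- contig == ct
        out[i] <- as.character(extractAt(genome[[ct]],
            IRanges::IRanges(start[i], end[i])))
    }
    out
}

.revcomp <- function(x) {
    as.character(reverseComplement(DNAStringSet(x)))
}

#' Emit aligned reads (SAM text) for a simulated scenario
#'
#' Linear fragments shorter than the read length emit fully-overlapping
#' mate pairs whose read length equals the fragment size (overlap-trimming
#' semantics); longer fragments emit full-length mates at the fragment
#' ends with |TLEN| equal to the fragment size. Junction reads from
#' planted circles emit one primary plus one supplementary record with
#' reciprocal SA tags encoding the split (3' portion of the circle first
#' in the query, then its 5' portion). Both fragment orientations occur;
#' reverse-strand records store the reference-oriented sequence, as SAM
#' requires. Soft clipping is not simulated for linear fragments.
#'
#' @param truth fragment truth table from \code{\link{sampleFragments}}.
#' @param junctions junction table from \code{\link{plantCircles}} (may be
#'   empty).
#' @param reference the (circle-modified) reference.
#' @param path output SAM path.
#' @param readLength platform read length (bp).
#' @return invisible \code{path}.
#' @export
emitAlignments <- function(truth, junctions, reference, path,
                           readLength = 150L) {
    genome <- reference$genome
    sl <- reference$seqlengths
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(sl), unname(sl)),
                "@PG\tID:cfsim\tPN:cfsim")
    lines <- character(0)
    if (nrow(truth)) {
        s <- truth$start0 + 1L
        e <- truth$end0
        w <- truth$size
        fwd <- truth$orientation == "+"
        short <- w < readLength
        # plus-strand mate coordinates
        pPlus <- s
        pMinus <- ifelse(short, s, e - readLength + 1L)
        lenP <- ifelse(short, w, readLength)
        seqPlus <- .refSlices(genome, truth$contig, pPlus,
                              pPlus + lenP - 1L)
        seqMinusFwd <- .refSlices(genome, truth$contig, pMinus,
                                  pMinus + lenP - 1L)
        cig <- paste0(lenP, "M")
        # read1 is the plus-strand mate when orientation is "+"
        flag1 <- ifelse(fwd, 99L, 83L)
        flag2 <- ifelse(fwd, 147L, 163L)
        pos1 <- ifelse(fwd, pPlus, pMinus)
        pos2 <- ifelse(fwd, pMinus, pPlus)
        seq1 <- ifelse(fwd, seqPlus, seqMinusFwd)
        seq2 <- ifelse(fwd, seqMinusFwd, seqPlus)
        tlen1 <- ifelse(fwd, w, -w)
        tlen2 <- -tlen1
        mk <- function(flag, pos, mpos, tl, sq)
            paste(truth$id, flag, truth$contig, pos, truth$mapq, cig,
                  "=", mpos, tl, sq, "*", sep = "\t")
        lines <- c(mk(flag1, pos1, pos2, tlen1, seq1),
                   mk(flag2, pos2, pos1, tlen2, seq2))
    }
    if (nrow(junctions)) {
        j <- junctions
        pA <- j$circleEnd - j$lenA + 1L           # 3' portion of circle
        pB <- j$circleStart                        # 5' portion
        seqA <- .refSlices(genome, j$contig, pA, j$circleEnd)
        seqB <- .refSlices(genome, j$contig, pB, pB + j$lenB - 1L)
        qseq <- paste0(seqA, seqB)                 # reference-oriented
        st <- j$orientation
        cigA <- paste0(j$lenA, "M", j$lenB, "S")
        cigB <- paste0(j$lenA, "S", j$lenB, "M")
        aPrimary <- j$lenA >= j$lenB
        flagBase <- ifelse(st == "-", 16L, 0L)
        saA <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", j$contig, pA, st, cigA)
        saB <- sprintf("SA:Z:%s,%d,%s,%s,60,0;", j$contig, pB, st, cigB)
        recA <- paste(j$readId,
                      flagBase + ifelse(aPrimary, 0L, 2048L),
                      j$contig, pA, 60L, cigA, "*", 0L, 0L, qseq, "*",
                      saB, sep = "\t")
        recB <- paste(j$readId,
                      flagBase + ifelse(aPrimary, 2048L, 0L),
                      j$contig, pB, 60L, cigB, "*", 0L, 0L, qseq, "*",
                      saA, sep = "\t")
        lines <- c(lines, recA, recB)
    }
    writeLines(c(header, lines), path)
    invisible(path)
}

#' Simulate one full scenario (reference, fragments, circles, alignments)
#'
#' Convenience wrapper: builds (or reuses) a reference, plants circles
#' (which edits junction flanks into the genome), samples the fragment
#' population, and emits the SAM plus truth tables. Byte-identical outputs
#' under a fixed seed.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param outDir output directory.
#' @param reference optional prebuilt reference (default: built from
#'   \code{config@seed}).
#' @param writeRef also write the reference FASTA and tracks.
#' @return list with the reference, fragments, truth, circles, junctions
#'   and file paths (sam, truthFragments, truthCircles, config).
#' @export
simulateScenario <- function(config, outDir, reference = NULL,
                             writeRef = TRUE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(reference))
        reference <- buildReference(seed = .deriveSeed(config@seed, 1L))
    circles <- .mkGRanges(character(), integer(), integer(),
                          seqlengths = reference$seqlengths)
    junctions <- data.table::data.table(readId = character(),
        circleId = integer(), contig = character(),
        circleStart = integer(), circleEnd = integer(), lenA = integer(),
        lenB = integer(), orientation = character())
    if (length(config@circles)) {
        pc <- plantCircles(config@circles, reference,
                           seed = .deriveSeed(config@seed, 2L),
                           readLength = config@readLength)
        circles <- pc$circles
        junctions <- pc$junctions
        reference <- pc$reference
    }
    samp <- sampleFragments(config, reference)
    samPath <- file.path(outDir, paste0(config@name, ".sam"))
    emitAlignments(samp$truth, junctions, reference, samPath,
                   readLength = config@readLength)
    truthFragPath <- file.path(outDir, "truth_fragments.tsv")
    data.table::fwrite(samp$truth, truthFragPath, sep = "\t")
    truthCircPath <- file.path(outDir, "truth_circles.tsv")
    data.table::fwrite(data.table::data.table(
        circleId = mcols(circles)$circleId,
        contig = as.character(seqnames(circles)),
        start0 = start(circles) - 1L, end0 = end(circles),
        size = mcols(circles)$size, sizeClass = mcols(circles)$sizeClass,
        junctionReadIds = mcols(circles)$junctionReadIds),
        truthCircPath, sep = "\t")
    cfgPath <- file.path(outDir, "scenario_config.yaml")
    yaml::write_yaml(configAsList(config), cfgPath)
    refPaths <- if (writeRef) writeReference(reference, outDir) else NULL
    list(reference = reference, fragments = samp$fragments,
         truth = samp$truth, circles = circles, junctions = junctions,
         paths = c(list(sam = samPath, truthFragments = truthFragPath,
                        truthCircles = truthCircPath, config = cfgPath),
                   as.list(refPaths)))
}

#' Scenario configuration as a plain list (for YAML serialization)
#' @param config a \code{\link{scenarioConfig}}.
#' @return named list of all scenario parameters.
#' @export
configAsList <- function(config) {
    sn <- methods::slotNames(config)
    out <- lapply(sn, function(s) {
        v <- methods::slot(config, s)
        if (s == "circles")
            lapply(v, function(cs) list(sizeClass = cs@sizeClass,
                sizePeaks = apply(cs@sizePeaks, 1, paste, collapse = ","),
                sizeWeights = cs@sizeWeights, count = cs@count,
                readsPerCircle = cs@readsPerCircle,
                junctionRepeatLen = cs@junctionRepeatLen))
        else if (s == "repeatEndBias") as.list(v)
        else v
    })
    stats::setNames(out, sn)
}
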