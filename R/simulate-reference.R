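#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   subseq subseq<- extractAt matchPattern writeXStringSet readDNAStringSet
NULL

# class layout of the synthetic repeat annotation: per-class genome
# fraction (scaled to the requested total), length range, and subfamilies.
# "(X)n" subfamilies get their literal tandem sequence written into the
# reference, as RepeatMasker simple/satellite annotations imply.
.repeatLayout <- function() {
    list(
        LINE = list(frac = 0.32, len = c(500L, 3000L),
            family = "L1", names = c("L1PA4", "L1MB7", "L2a")),
        SINE = list(frac = 0.24, len = c(100L, 300L),
            family = "Alu", names = c("AluY", "AluSx", "MIRb")),
        LTR = list(frac = 0.16, len = c(200L, 1000L),
            family = "ERVL", names = c("MLT1K", "LTR16A")),
        Simple_repeat = list(frac = 0.12, len = c(30L, 200L),
            family = "Simple_repeat",
            names = c("(TCCAT)n", "(AT)n", "(CA)n", "(GAGTG)n")),
        Satellite = list(frac = 0.08, len = c(200L, 1500L),
            family = "centr", names = c("(CATTC)n", "ALR/Alpha", "HSATII")),
        Low_complexity = list(frac = 0.08, len = c(30L, 150L),
            family = "Low_complexity", names = c("A-rich", "GC_rich")))
}

.randomSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample a non-overlapping interval of width w in [margin, L - margin]
# against an occupancy mask; returns start or NA after maxTry failures
.placeInterval <- function(occupied, w, margin, maxTry = 200L) {
    L <- length(occupied)
    for (i in seq_len(maxTry)) {
        s <- sample.int(L - 2L * margin - w, 1L) + margin
        if (!any(occupied[s:(s + w - 1L)])) return(s)
    }
    NA_integer_
}

#' Build a synthetic reference genome with annotation tracks
#'
#' Emits a random-sequence nuclear contig plus a mitochondrial contig, and
#' plants non-overlapping annotation tracks: repeat intervals (classes
#' LINE, SINE, LTR, Simple_repeat, Satellite, Low_complexity, with
#' subfamilies including "(TCCAT)n" and "(CATTC)n" whose literal tandem
#' sequence is written into the reference), TSS points and TU intervals
#' with strand, TFBS points, super-enhancer (SE) intervals, blacklist
#' intervals and tandem-duplication intervals. Fully deterministic under
#' the seed.
#'
#' @param seed RNG seed.
#' @param genomeSize nuclear contig size in bp (default 2 Mb).
#' @param mitoSize mitochondrial contig size (default 16,500 bp).
#' @param repeatFraction target fraction of the nuclear contig covered by
#'   the repeat track (default 0.25); achieved within about 1 percent.
#' @param contigName,mitoContig contig names.
#' @return list with \code{genome} (DNAStringSet), \code{tracks} (named
#'   list of GRanges: repeats, tss, tu, tfbs, se, blacklist, tandem_dups),
#'   \code{mitoContig}, \code{seqlengths}.
#' @export
buildReference <- function(seed = 1L, genomeSize = 2000000L,
                           mitoSize = 16500L, repeatFraction = 0.25,
                           contigName = "chr1", mitoContig = "chrM") {
    .stopIfNot(genomeSize >= 100000L,
               "genomeSize must be at least 100 kb to place the tracks")
    set.seed(seed)
    nuc <- .randomSeq(genomeSize)
    mito <- .randomSeq(mitoSize)
    seqlengths <- stats::setNames(c(genomeSize, mitoSize),
                                  c(contigName, mitoContig))

    layout <- .repeatLayout()
    occupied <- logical(genomeSize)
    margin <- 2000L
    reps <- list()
    for (cls in names(layout)) {
        info <- layout[[cls]]
        target <- round(info$frac * repeatFraction * genomeSize)
        placed <- 0L
        rows <- list()
        while (placed < target) {
            w <- sample(info$len[1]:info$len[2], 1L)
            if (placed + w > target + info$len[1])
                w <- max(info$len[1], target - placed)
            s <- .placeInterval(occupied, w, margin)
            if (is.na(s))
                stop("genome too small to place the requested repeat track")
            occupied[s:(s + w - 1L)] <- TRUE
            nm <- sample(info$names, 1L)
            rows[[length(rows) + 1L]] <-
                data.frame(start = s, end = s + w - 1L, repName = nm,
                           repClass = cls, repFamily = info$family)
            placed <- placed + w
        }
        reps[[cls]] <- do.call(rbind, rows)
    }
    repdf <- do.call(rbind, reps)
    nuc <- DNAString(nuc)
    # write literal tandem sequence into "(X)n" subfamily intervals
    tandem <- which(grepl("^\\(.+\\)n$", repdf$repName))
    if (length(tandem)) {
        vals <- vapply(tandem, function(i) {
            unit <- sub("^\\((.+)\\)n$", "\\1", repdf$repName[i])
            w <- repdf$end[i] - repdf$start[i] + 1L
            substr(strrep(unit, ceiling(w / nchar(unit))), 1L, w)
        }, character(1))
        nuc <- Biostrings::replaceAt(nuc,
            IRanges::IRanges(repdf$start[tandem], repdf$end[tandem]),
            DNAStringSet(vals))
    }
    repeats <- .mkGRanges(contigName, repdf$start, repdf$end,
                          seqlengths = seqlengths)
    mcols(repeats)$repName <- repdf$repName
    mcols(repeats)$repClass <- repdf$repClass
    mcols(repeats)$repFamily <- repdf$repFamily
    repeats <- sort(repeats)

    placeTrack <- function(count, lenRange, stranded = FALSE) {
        occ <- logical(genomeSize)
        st <- integer(count); en <- integer(count)
        for (i in seq_len(count)) {
            w <- if (lenRange[1] == lenRange[2]) lenRange[1]
                 else sample(lenRange[1]:lenRange[2], 1L)
            s <- .placeInterval(occ, w, margin)
            if (is.na(s)) stop("genome too small to place a track")
            occ[s:(s + w - 1L)] <- TRUE
            st[i] <- s; en[i] <- s + w - 1L
        }
        strand <- if (stranded) sample(c("+", "-"), count, replace = TRUE)
                  else "*"
        sort(.mkGRanges(contigName, st, en, strand = strand,
                        seqlengths = seqlengths))
    }
    tu <- placeTrack(200L, c(1000L, 5000L), stranded = TRUE)
    tss <- placeTrack(300L, c(1L, 1L), stranded = TRUE)
    tfbs <- placeTrack(400L, c(1L, 1L))
    se <- placeTrack(25L, c(3000L, 10000L))
    blacklist <- placeTrack(20L, c(1000L, 5000L))
    dups <- placeTrack(20L, c(1000L, 5000L))

    genome <- DNAStringSet(list(nuc, DNAString(mito)))
    names(genome) <- c(contigName, mitoContig)
    list(genome = genome,
         tracks = list(repeats = repeats, tss = tss, tu = tu, tfbs = tfbs,
                       se = se, blacklist = blacklist, tandem_dups = dups),
         mitoContig = mitoContig, seqlengths = seqlengths, seed = seed)
}

#' Write a synthetic reference and its tracks to a directory
#'
#' FASTA for the genome, BED6 for point/interval tracks, and the
#' RepeatMasker-like TSV for the repeat track.
#'
#' @param reference result of \code{\link{buildReference}}.
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
writeReference <- function(reference, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"))
    writeXStringSet(reference$genome, paths["genome"])
    for (nm in names(reference$tracks)) {
        gr <- reference$tracks[[nm]]
        if (nm == "repeats") {
            p <- file.path(dir, "repeats.tsv")
            writeRepeatTable(gr, p)
        } else {
            p <- file.path(dir, paste0(nm, ".bed"))
            writeBed(gr, p)
        }
        paths[nm] <- p
    }
    invisible(paths)
}
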