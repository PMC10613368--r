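# Shared fixtures, built once per session and cached.

.fixtures <- new.env(parent = emptyenv())

# the standard 2 Mb synthetic reference (seed 1)
refFixture <- function() {
    if (is.null(.fixtures$ref))
        .fixtures$ref <- buildReference(seed = 1L)
    .fixtures$ref
}

# write SAM text from a header + body lines
writeSamLines <- function(body, path = tempfile(fileext = ".sam"),
                          contigs = c(chr1 = 10000L, chrM = 1000L)) {
    header <- c("@HD\tVN:1.6\tSO:unknown",
                sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                        unname(contigs)))
    writeLines(c(header, body), path)
    path
}

# one proper pair as SAM body lines (1-based pos; sub-readLength fragment
# semantics when seqLen < 150)
samPair <- function(qname, contig, pos, size, seqLen = min(size, 150L),
                    mapq = 60L, orient = "+") {
    seq1 <- strrep("A", seqLen)
    posR <- pos + size - seqLen
    cig <- paste0(seqLen, "M")
    if (orient == "+") {
        c(paste(qname, 99L, contig, pos, mapq, cig, "=", posR, size,
                seq1, "*", sep = "\t"),
          paste(qname, 147L, contig, posR, mapq, cig, "=", pos, -size,
                seq1, "*", sep = "\t"))
    } else {
        c(paste(qname, 83L, contig, posR, mapq, cig, "=", pos, -size,
                seq1, "*", sep = "\t"),
          paste(qname, 163L, contig, pos, mapq, cig, "=", posR, size,
                seq1, "*", sep = "\t"))
    }
}

# FragmentSet from bare vectors (test construction shortcut)
makeFragments <- function(contig, start, end, strand = "+",
                          mapq = 60L, origin = NULL,
                          seqlengths = c(chr1 = 10000L),
                          mitoContig = "chrM") {
    n <- length(start)
    gr <- GenomicRanges::GRanges(rep(contig, length.out = n),
        IRanges::IRanges(start, end),
        strand = rep(strand, length.out = n), seqlengths = seqlengths)
    if (is.null(origin))
        origin <- ifelse(contig == mitoContig, "mito", "nuclear")
    sz <- as.integer(end - start + 1L)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        id = sprintf("T%05d", seq_len(n)), size = sz,
        sizeSource = ifelse(sz < 150L, "read_length", "insert_size"),
        mapq = rep(as.integer(mapq), length.out = n),
        origin = rep(origin, length.out = n))
    new("FragmentSet", fragments = gr, mitoContig = mitoContig)
}

# fragments planting a TSS-style footprint: focal fragments centered on
# anchors, background uniform; "depleted" instead rejects near anchors
plantFootprintFragments <- function(anchors, nFocal, nBackground,
                                    fragSize = 80L, mode = c("enriched",
                                    "depleted"), seqlen = 2000000L,
                                    seed = 1L) {
    mode <- match.arg(mode)
    set.seed(seed)
    margin <- 2000L
    bgStart <- sample.int(seqlen - 2L * margin, nBackground) + margin
    starts <- bgStart
    if (mode == "enriched") {
        ctr <- sample(GenomicRanges::start(anchors), nFocal,
                      replace = TRUE)
        starts <- c(starts, ctr - fragSize %/% 2L)
    } else {
        near <- unlist(lapply(GenomicRanges::start(anchors),
            function(p) (p - 400L):(p + 400L)))
        keep <- !(starts %in% near)
        starts <- starts[keep]
    }
    makeFragments("chr1", starts, starts + fragSize - 1L,
                  seqlengths = c(chr1 = seqlen))
}

# cached full-scale scenario runs shared by the acceptance tests
plasmaRun <- function() {
    if (is.null(.fixtures$plasma)) {
        dir <- file.path(tempdir(), "accept_plasma")
        cfg <- scenarioConfig("plasma_like", nFragments = 200000L,
                              seed = 42L)
        sim <- simulateScenario(cfg, dir)
        aln <- readAlignments(sim$paths$sam)
        frags <- suppressMessages(pairFragments(aln))
        .fixtures$plasma <- list(sim = sim, aln = aln, frags = frags,
            nuclear = sizeHistogram(frags, "nuclear"))
    }
    .fixtures$plasma
}

proliferativeRun <- function() {
    if (is.null(.fixtures$prolif)) {
        dir <- file.path(tempdir(), "accept_prolif")
        cfg <- scenarioConfig("proliferative", nFragments = 200000L,
                              seed = 42L)
        sim <- simulateScenario(cfg, dir)
        aln <- readAlignments(sim$paths$sam)
        frags <- suppressMessages(pairFragments(aln))
        .fixtures$prolif <- list(sim = sim, frags = frags,
            nuclear = sizeHistogram(frags, "nuclear"))
    }
    .fixtures$prolif
}

circleRun <- function() {
    if (is.null(.fixtures$circ)) {
        dir <- file.path(tempdir(), "accept_circ")
        cfg <- scenarioConfig("apoptotic", nFragments = 20000L,
                              seed = 42L,
                              circles = list(circleSpec(count = 200L)))
        sim <- simulateScenario(cfg, dir)
        aln <- readAlignments(sim$paths$sam)
        ev <- collectJunctions(aln)
        calls <- suppressMessages(filterTandemDuplications(
            clusterCircleCalls(ev),
            sim$reference$tracks$tandem_dups))
        .fixtures$circ <- list(sim = sim, aln = aln, evidence = ev,
                               calls = calls)
    }
    .fixtures$circ
}
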