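test_that("junction collection requires the circle split pattern", {
    # a junction over 0-based circle [500,800): downstream segment first
    body <- c(
        paste("j1", 0L, "chr1", 701L, 60L, "100M50S", "*", 0L, 0L,
              strrep("A", 150L), "*", "SA:Z:chr1,501,+,100S50M,60,0;",
              sep = "\t"),
        paste("j1", 2048L, "chr1", 501L, 60L, "100S50M", "*", 0L, 0L,
              strrep("A", 150L), "*", "SA:Z:chr1,701,+,100M50S,60,0;",
              sep = "\t"),
        # ordinary linear read: no supplementary, no evidence
        samPair("lin1", "chr1", 1001L, 167L),
        # split across two contigs: ignored
        paste("x1", 0L, "chr1", 2001L, 60L, "100M50S", "*", 0L, 0L,
              strrep("A", 150L), "*", "SA:Z:chrM,11,+,100S50M,60,0;",
              sep = "\t"),
        paste("x1", 2048L, "chrM", 11L, 60L, "100S50M", "*", 0L, 0L,
              strrep("A", 150L), "*", "SA:Z:chr1,2001,+,100M50S,60,0;",
              sep = "\t"))
    aln <- readAlignments(writeSamLines(body))
    ev <- collectJunctions(aln)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$readId, "j1")
    expect_equal(ev$leftBreak, 501L)    # 0-based 500
    expect_equal(ev$rightBreak, 800L)   # 0-based exclusive 800

    # upstream-first split (read-through, not a junction): ignored
    body2 <- c(
        paste("r1", 0L, "chr1", 501L, 60L, "50M100S", "*", 0L, 0L,
              strrep("A", 150L), "*", "SA:Z:chr1,701,+,50S100M,60,0;",
              sep = "\t"),
        paste("r1", 2048L, "chr1", 701L, 60L, "50S100M", "*", 0L, 0L,
              strrep("A", 150L), "*", "SA:Z:chr1,501,+,50M100S,60,0;",
              sep = "\t"))
    expect_equal(nrow(collectJunctions(
        readAlignments(writeSamLines(body2)))), 0L)
})

test_that("evidence clustering respects tolerance and support", {
    ev <- data.table::data.table(
        readId = paste0("r", 1:5), contig = "chr1",
        leftBreak = c(500L, 501L, 499L, 500L, 502L),
        rightBreak = c(800L, 800L, 801L, 799L, 800L))
    calls <- clusterCircleCalls(ev, tol = 5L, minSupport = 2L)
    expect_equal(length(calls), 1L)
    gr <- circleCalls(calls)
    expect_equal(S4Vectors::mcols(gr)$support, 5L)
    expect_equal(GenomicRanges::start(gr), 500L)
    expect_equal(GenomicRanges::end(gr), 800L)

    apart <- data.table::data.table(
        readId = c("a", "b"), contig = "chr1",
        leftBreak = c(500L, 512L), rightBreak = c(800L, 812L))
    expect_equal(length(clusterCircleCalls(apart, tol = 5L,
                                           minSupport = 2L)), 0L)
})

test_that("tandem-duplication filtering is half-open at the boundary", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(100L, 301L), c(300L, 500L)))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        support = c(3L, 3L), readIds = c("a,b,c", "d,e,f"),
        length = GenomicRanges::width(gr))
    calls <- new("CircleCallSet", calls = gr)
    # dup 0-based [250,301): overlaps the first call, touches the second
    dup <- GenomicRanges::GRanges("chr1", IRanges::IRanges(251L, 300L))
    kept <- suppressMessages(filterTandemDuplications(calls, dup))
    expect_equal(length(kept), 1L)
    expect_equal(GenomicRanges::start(circleCalls(kept)), 301L)
})

test_that("planted circles are recovered sensitively at exact coordinates", {
    run <- circleRun()
    tc <- run$sim$circles
    nReads <- lengths(strsplit(S4Vectors::mcols(tc)$junctionReadIds,
                               ","))
    nReads[S4Vectors::mcols(tc)$junctionReadIds == ""] <- 0L
    eligible <- tc[nReads >= 2L]
    calls <- circleCalls(run$calls)
    hits <- GenomicRanges::findOverlaps(eligible, calls,
                                        type = "equal", maxgap = 5L)
    sens <- length(unique(S4Vectors::queryHits(hits))) /
        length(eligible)
    expect_gte(sens, 0.95)
    # truth-flagged dup/blacklist subset is empty by construction, so
    # every call matches a planted circle (no false calls)
    back <- GenomicRanges::findOverlaps(calls, tc, type = "equal",
                                        maxgap = 5L)
    expect_equal(length(unique(S4Vectors::queryHits(back))),
                 length(calls))
})

test_that("a circle-free scenario yields zero evidence and zero calls", {
    run <- plasmaRun()
    ev <- collectJunctions(run$aln)
    expect_equal(nrow(ev), 0L)
    expect_equal(length(clusterCircleCalls(ev)), 0L)
})

test_that("length spectra summarize calls with reused detectors", {
    gr <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(rep(1000L, 10L), width = 500L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        support = rep(2L, 10L), readIds = "x,y",
        length = GenomicRanges::width(gr))
    sp <- lengthSpectrum(new("CircleCallSet", calls = gr))
    expect_equal(sp$propUnderCutoff, 1)
    expect_equal(sp$cumulative$proportion[
        sp$cumulative$length >= 500L][1], 1)
    expect_true(all(sp$lengths == 500L))

    grL <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(rep(1000L, 5L), width = 5000L))
    S4Vectors::mcols(grL) <- S4Vectors::DataFrame(
        support = rep(2L, 5L), readIds = "x,y",
        length = GenomicRanges::width(grL))
    expect_equal(lengthSpectrum(
        new("CircleCallSet", calls = grL))$propUnderCutoff, 0)

    # per-read weighting repeats lengths by support
    spR <- lengthSpectrum(new("CircleCallSet", calls = gr),
                          weight = "per_read")
    expect_equal(length(spR$lengths), 20L)
})

test_that("junction microhomology recovers the planted direct repeat", {
    run <- circleRun()
    jc <- junctionCharacterize(run$calls, run$sim$reference,
        repeatTrack = run$sim$reference$tracks$repeats)
    modal <- as.integer(names(sort(table(jc$microhomology),
                                   decreasing = TRUE))[1])
    expect_equal(modal, 4L)
    expect_true(all(jc$microhomology >= 4L))

    # random breakpoints: match lengths are geometric, mode 0
    set.seed(13)
    ref <- run$sim$reference
    pos <- sample.int(1900000L, 300L) + 10000L
    grR <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(pos, pos + 300L))
    S4Vectors::mcols(grR) <- S4Vectors::DataFrame(
        support = rep(2L, 300L), readIds = "x,y",
        length = GenomicRanges::width(grR))
    jcR <- junctionCharacterize(new("CircleCallSet", calls = grR), ref)
    expect_equal(as.integer(names(sort(table(jcR$microhomology),
                                       decreasing = TRUE))[1]), 0L)
    expect_lt(mean(jcR$microhomology), 1)
})

test_that("circle CPM normalizes support by mapped reads", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000L, 1500L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(support = 10L,
        readIds = "r", length = 501L)
    calls <- new("CircleCallSet", calls = gr)
    expect_equal(circleCPM(calls, 1e6)$overall, 10)
    expect_equal(circleCPM(calls, 1e6)$micro, 10)
    expect_equal(circleCPM(calls, 1e6)$large, 0)
    expect_error(circleCPM(calls, 0), "positive")
    empty <- new("CircleCallSet",
        calls = GenomicRanges::GRanges())
    expect_equal(circleCPM(empty, 1e6)$overall, 0)
})

test_that("CPM is invariant to sequencing depth at fixed circle content", {
    ref <- buildReference(seed = 41L)
    mkRun <- function(nFrag, seed) {
        cfg <- scenarioConfig("apoptotic", nFragments = nFrag,
            seed = seed, circles = list(circleSpec(count = 40L,
                readsPerCircle = 5 * nFrag / 10000)))
        sim <- simulateScenario(cfg, tempfile(), writeRef = FALSE)
        aln <- readAlignments(sim$paths$sam)
        calls <- clusterCircleCalls(collectJunctions(aln))
        circleCPM(calls, sum(!aln$isSupplementary))$overall
    }
    cpm1 <- mkRun(10000L, 51L)
    cpm2 <- mkRun(20000L, 52L)
    expect_lt(abs(cpm2 - cpm1) / cpm1, 0.35)
})
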