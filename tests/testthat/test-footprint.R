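test_that("binned coverage increments every overlapped bin once", {
    # 0-based [0,25) covers 10 bp bins 0,1,2
    fs <- makeFragments("chr1", 1L, 25L, seqlengths = c(chr1 = 100L))
    cov <- binnedCoverage(fs, mapqMin = 0L)
    expect_equal(cov@bins$chr1, c(1, 1, 1, rep(0, 7)))

    lowQ <- makeFragments("chr1", 1L, 25L, mapq = 29L,
                          seqlengths = c(chr1 = 100L))
    covQ <- binnedCoverage(lowQ, mapqMin = 30L)
    expect_equal(sum(covQ@bins$chr1), 0)
    expect_equal(covQ@nUsed, 0L)

    empty <- makeFragments("chr1", integer(0), integer(0),
                           seqlengths = c(chr1 = 100L))
    expect_equal(sum(binnedCoverage(empty)@bins$chr1), 0)
})

test_that("BPM normalization conserves a total of 1e6 and is scale-free", {
    fs <- makeFragments("chr1", c(1L, 1L, 11L, 21L),
                        c(10L, 10L, 20L, 30L),
                        seqlengths = c(chr1 = 30L))
    cov <- binnedCoverage(fs, mapqMin = 0L)
    expect_equal(cov@bins$chr1, c(2, 1, 1))
    bpm <- bpmNormalize(cov)
    expect_equal(bpm@bins$chr1, c(500000, 250000, 250000))
    expect_equal(sum(unlist(bpm@bins)), 1e6)

    doubled <- cov
    doubled@bins$chr1 <- cov@bins$chr1 * 2
    expect_equal(bpmNormalize(doubled)@bins$chr1, bpm@bins$chr1)

    zero <- binnedCoverage(makeFragments("chr1", integer(0), integer(0),
        seqlengths = c(chr1 = 100L)))
    expect_error(bpmNormalize(zero), "all-zero")
})

test_that("point metaprofiles are flat on uniform coverage and flip strand", {
    cov <- new("BinnedCoverage", binSize = 10L,
               bins = list(chr1 = rep(5, 1000L)), normalized = FALSE,
               nUsed = 0L, seqlengths = c(chr1 = 10000L))
    anchors <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(3000L, 6000L), width = 1L), strand = "+")
    mp <- metaprofilePoint(cov, anchors, flank = 500L)
    expect_equal(unname(meanProfile(mp)), rep(5, 100L))

    # asymmetric coverage: minus-strand profile is the reverse
    cov@bins$chr1 <- seq_len(1000L) / 10
    plus <- metaprofilePoint(cov, GenomicRanges::GRanges("chr1",
        IRanges::IRanges(5000L, width = 1L), strand = "+"), flank = 500L)
    minus <- metaprofilePoint(cov, GenomicRanges::GRanges("chr1",
        IRanges::IRanges(5000L, width = 1L), strand = "-"), flank = 500L)
    expect_equal(unname(minus@values[1, ]), rev(unname(plus@values[1, ])))

    far <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(10L, 5000L), width = 1L))
    expect_message(mp2 <- metaprofilePoint(cov, far, flank = 500L),
                   "dropped")
    expect_equal(mp2@anchorsN, 1L)
})

test_that("planted TSS footprints show NFR enrichment and NBR depletion", {
    anchors <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(100000L, 1900000L, by = 20000L),
                         width = 1L), strand = "+")
    nfr <- plantFootprintFragments(anchors, nFocal = 4000L,
                                   nBackground = 8000L, seed = 2L)
    nbr <- plantFootprintFragments(anchors, nFocal = 0L,
        nBackground = 12000L, mode = "depleted", seed = 3L)
    mpN <- metaprofilePoint(bpmNormalize(binnedCoverage(nfr,
        mapqMin = 0L)), anchors)
    mpB <- metaprofilePoint(bpmNormalize(binnedCoverage(nbr,
        mapqMin = 0L)), anchors)
    profN <- meanProfile(mpN); profB <- meanProfile(mpB)
    ctr <- length(profN) %/% 2L + c(0L, 1L)
    edge <- c(1:10, (length(profN) - 9L):length(profN))
    expect_gt(mean(profN[ctr]), 2 * mean(profN[edge]))
    expect_lt(mean(profB[ctr]), 0.5 * mean(profB[edge]))
})

test_that("scaled metaprofiles interpolate region bodies", {
    cov <- new("BinnedCoverage", binSize = 10L,
               bins = list(chr1 = rep(3, 2000L)), normalized = FALSE,
               nUsed = 0L, seqlengths = c(chr1 = 20000L))
    reg <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(5001L, 8000L), strand = "+")
    mp <- metaprofileScaled(cov, reg, bodyBins = 50L, flank = 200L)
    expect_equal(unname(mp@values[1, ]), rep(3, 50L + 2L * 20L))

    # linear ramp across a 10-bin region: interpolation oracle
    cov@bins$chr1 <- rep(0, 2000L)
    cov@bins$chr1[501:510] <- 1:10
    reg2 <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(5001L, 5100L), strand = "+")
    mp2 <- metaprofileScaled(cov, reg2, bodyBins = 19L, flank = 100L)
    body <- mp2@values[1, 11:29]
    expect_equal(unname(body), seq(1, 10, by = 0.5))
    expect_false(is.unsorted(body))

    tiny <- GenomicRanges::GRanges("chr1", IRanges::IRanges(601L, 605L))
    expect_warning(
        expect_error(metaprofileScaled(cov, tiny), "usable"),
        "shorter")
})

test_that("region matrices are depth invariant with matched samples", {
    fs <- makeFragments("chr1", seq(101L, 9001L, by = 100L),
                        seq(180L, 9080L, by = 100L),
                        seqlengths = c(chr1 = 10000L))
    cov1 <- bpmNormalize(binnedCoverage(fs, mapqMin = 0L))
    # doubled depth: same fragments twice
    gr <- fragments(fs)
    fs2 <- new("FragmentSet", fragments = c(gr, gr),
               mitoContig = "chrM")
    cov2 <- bpmNormalize(binnedCoverage(fs2, mapqMin = 0L))
    regions <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1001L, 5001L), c(2000L, 6000L)))
    m <- regionMatrix(list(a = cov1, b = cov2), regions)
    expect_equal(m["a", ], m["b", ])
    expect_equal(nrow(m), 2L)
    # identical samples give identical rows
    m2 <- regionMatrix(list(a = cov1, b = cov1), regions)
    expect_equal(m2["a", ], m2["b", ])
    expect_equal(unname(attr(m2, "zeroVariance")), c(1L, 2L))
})
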