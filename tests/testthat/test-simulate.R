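test_that("reference building is byte-deterministic under a fixed seed", {
    d1 <- tempfile(); d2 <- tempfile()
    p1 <- writeReference(buildReference(seed = 11L), d1)
    p2 <- writeReference(buildReference(seed = 11L), d2)
    for (nm in names(p1))
        expect_equal(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), info = nm)
})

test_that("repeat track hits its base-fraction target within 1 percent", {
    ref <- refFixture()
    rmsk <- ref$tracks$repeats
    frac <- sum(GenomicRanges::width(rmsk)) /
        ref$seqlengths[["chr1"]]
    expect_lt(abs(frac - 0.25), 0.01)
    # and the track is internally non-overlapping
    expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(rmsk))),
                 sum(GenomicRanges::width(rmsk)))
})

test_that("simple-repeat intervals carry their literal tandem sequence", {
    ref <- refFixture()
    rmsk <- ref$tracks$repeats
    tc <- rmsk[S4Vectors::mcols(rmsk)$repName == "(TCCAT)n"][1]
    seq <- as.character(Biostrings::extractAt(ref$genome[["chr1"]],
        IRanges::IRanges(GenomicRanges::start(tc),
                         GenomicRanges::end(tc))))
    w <- GenomicRanges::width(tc)
    expect_equal(seq,
                 substr(strrep("TCCAT", ceiling(w / 5) ), 1L, w))
})

test_that("fragment sampling honors the scenario mixture", {
    ref <- refFixture()
    empty <- sampleFragments(
        scenarioConfig("plasma_like", nFragments = 0L), ref)
    expect_equal(length(empty$fragments), 0L)
    expect_equal(nrow(empty$truth), 0L)

    cfg <- scenarioConfig("plasma_like", nFragments = 60000L, seed = 5L)
    s <- sampleFragments(cfg, ref)
    truth <- s$truth
    # truth sizes equal end - start (0-based half-open)
    expect_true(all(truth$size == truth$end0 - truth$start0))
    nuc <- truth$size[truth$contig == "chr1"]
    expect_equal(as.integer(names(which.max(table(nuc)))), 167L)
    # mito fragments all sub-100 bp on the mito contig
    mito <- truth[truth$component == "mito", ]
    expect_true(all(mito$contig == "chrM"))
    expect_true(all(mito$size >= 30L & mito$size <= 100L))
})

test_that("short-fragment mass matches the analytic mixture integral", {
    ref <- refFixture()
    cfg <- scenarioConfig("proliferative", nFragments = 100000L,
                          seed = 9L)
    s <- sampleFragments(cfg, ref)
    nuc <- s$truth[s$truth$contig == "chr1", ]
    obs <- mean(nuc$size <= 118L)
    expect_lt(abs(obs - expectedMassBelow(cfg, 118L)), 0.03)
})

test_that("circle planting produces truth-consistent junction reads", {
    ref <- buildReference(seed = 21L)
    one <- plantCircles(list(circleSpec(count = 1L,
        readsPerCircle = 5L)), ref, seed = 3L)
    nReads <- nrow(one$junctions)
    ids <- strsplit(S4Vectors::mcols(one$circles)$junctionReadIds,
                    ",")[[1]]
    expect_equal(length(ids), nReads)
    expect_setequal(ids, one$junctions$readId)

    none <- plantCircles(list(circleSpec(count = 0L)), ref, seed = 3L)
    expect_equal(nrow(none$junctions), 0L)

    many <- plantCircles(list(circleSpec(count = 200L)), ref, seed = 4L)
    sz <- S4Vectors::mcols(many$circles)$size
    expect_gt(sum(abs(sz - 202L) <= 9L), 80L)
    expect_gt(sum(abs(sz - 349L) <= 9L), 40L)
    expect_equal(length(many$circles), 200L)
    # circles avoid blacklist and tandem-duplication tracks
    avoid <- c(ref$tracks$blacklist, ref$tracks$tandem_dups)
    expect_equal(sum(IRanges::overlapsAny(many$circles, avoid)), 0L)
})

test_that("emitted mates follow the trimming semantics", {
    ref <- refFixture()
    truth <- data.table::data.table(
        id = c("a", "b"), contig = "chr1",
        start0 = c(1000L, 2000L), end0 = c(1120L, 2250L),
        size = c(120L, 250L), component = "ladder",
        orientation = "+", motifPlanted = FALSE, mapq = 60L)
    p <- tempfile(fileext = ".sam")
    emitAlignments(truth, data.table::data.table(), ref, p)
    aln <- readAlignments(p)
    a <- aln[aln$qname == "a", ]
    expect_equal(nchar(a$seq), c(120L, 120L))
    expect_equal(abs(a$tlen), c(120L, 120L))
    b <- aln[aln$qname == "b", ]
    expect_equal(nchar(b$seq), c(150L, 150L))
    expect_equal(abs(b$tlen), c(250L, 250L))
})

test_that("junction reads recompose the full read via their SA tags", {
    ref <- buildReference(seed = 31L)
    pc <- plantCircles(list(circleSpec(count = 1L,
        readsPerCircle = 4L)), ref, seed = 8L)
    p <- tempfile(fileext = ".sam")
    emitAlignments(data.table::data.table(id = character(),
        contig = character(), start0 = integer(), end0 = integer(),
        size = integer(), component = character(),
        orientation = character(), motifPlanted = logical(),
        mapq = integer()), pc$junctions, pc$reference, p)
    aln <- readAlignments(p)
    j <- pc$junctions[1, ]
    rec <- aln[aln$qname == j$readId, ]
    expect_equal(nrow(rec), 2L)
    expect_equal(sum(rec$isSupplementary), 1L)
    # oracle: concatenating the two M-segments in query order must
    # reproduce the read sequence stored in both records
    prim <- rec[!rec$isSupplementary, ]
    supp <- rec[rec$isSupplementary, ]
    sa <- parseSATag(prim$sa)
    expect_equal(sa$pos, supp$pos)
    expect_equal(sa$cigar, supp$cigar)
    genome <- pc$reference$genome
    segA <- as.character(Biostrings::extractAt(genome[["chr1"]],
        IRanges::IRanges(j$circleEnd - j$lenA + 1L, j$circleEnd)))
    segB <- as.character(Biostrings::extractAt(genome[["chr1"]],
        IRanges::IRanges(j$circleStart, j$circleStart + j$lenB - 1L)))
    expect_equal(prim$seq, paste0(segA, segB))
    expect_equal(supp$seq, prim$seq)
})

test_that("scenario simulation is byte-identical under a fixed seed", {
    cfg <- scenarioConfig("proliferative", nFragments = 3000L,
                          seed = 13L,
                          circles = list(circleSpec(count = 10L)))
    d1 <- tempfile(); d2 <- tempfile()
    s1 <- simulateScenario(cfg, d1)
    s2 <- simulateScenario(cfg, d2)
    for (nm in names(s1$paths))
        expect_equal(unname(tools::md5sum(s1$paths[[nm]])),
                     unname(tools::md5sum(s2$paths[[nm]])), info = nm)
})

test_that("pipeline sizes equal truth sizes for all concordant fragments", {
    cfg <- scenarioConfig("apoptotic", nFragments = 8000L, seed = 17L)
    sim <- simulateScenario(cfg, tempfile())
    frags <- suppressMessages(pairFragments(readAlignments(
        sim$paths$sam)))
    expect_equal(length(frags), 8000L)
    gr <- fragments(frags)
    m <- match(S4Vectors::mcols(gr)$id, sim$truth$id)
    expect_false(anyNA(m))
    expect_equal(S4Vectors::mcols(gr)$size, sim$truth$size[m])
    expect_equal(GenomicRanges::start(gr), sim$truth$start0[m] + 1L)
    expect_equal(GenomicRanges::end(gr), sim$truth$end0[m])
})
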