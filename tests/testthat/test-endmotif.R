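test_that("terminus sampling is uniform, clamped and deterministic", {
    fs <- makeFragments("chr1", seq(101L, 1001L, by = 100L),
                        seq(180L, 1080L, by = 100L))
    s5 <- sampleTermini(fs, 5L, seed = 3L)
    expect_equal(length(s5), 5L)
    expect_equal(anyDuplicated(S4Vectors::mcols(fragments(s5))$id), 0L)
    expect_warning(all10 <- sampleTermini(fs, 5000000L, seed = 3L),
                   "taking all")
    expect_equal(length(all10), 10L)
    s5b <- sampleTermini(fs, 5L, seed = 3L)
    expect_identical(fragments(s5), fragments(s5b))
    # the default draw matches the depth-normalization sampling count
    expect_equal(eval(formals(sampleTermini)$n), 5000000L)
})

test_that("flank extraction follows the breakpoint window definition", {
    ref <- list(genome = Biostrings::DNAStringSet(c(
        chr1 = "ACGTACGTAC")))
    # 0-based fragment [2,8) = 1-based [3,8], w = 2
    fr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3L, 8L),
                                 strand = "+")
    fl <- extractFlanks(ref, fr, wOut = 2L, wIn = 2L)
    expect_equal(fl$fivePrime, "ACGT")    # outside "AC" + inside "GT"
    expect_equal(fl$threePrime, "GTAC")   # inside "GT" + outside "AC"

    # fragment at the contig start pads the outside with N
    fr0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1L, 6L),
                                  strand = "+")
    fl0 <- extractFlanks(ref, fr0, wOut = 2L, wIn = 2L)
    expect_equal(substr(fl0$fivePrime, 1L, 2L), "NN")

    # minus orientation: role swap, reverse complement (string oracle)
    frM <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3L, 8L),
                                  strand = "-")
    flM <- extractFlanks(ref, frM, wOut = 2L, wIn = 2L)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    expect_equal(flM$fivePrime, rc(fl$threePrime))
    expect_equal(flM$threePrime, rc(fl$fivePrime))
})

test_that("PFMs normalize to unit columns with bounded information", {
    pfm <- buildPFM(c("ACG", "ACG"))
    expect_equal(unname(colSums(pfm$freq)), rep(1, 3))
    expect_equal(unname(pfm$info), rep(2, 3))

    mix <- buildPFM(c("AAAA", "CCCC", "GGGG", "TTTT"))
    expect_equal(unname(mix$info), rep(0, 4))

    # N bases leave the column totals
    withN <- buildPFM(c("AN", "AC"))
    expect_equal(unname(withN$colTotals), c(2, 1))
    expect_true(all(withN$info >= 0 & withN$info <= 2))

    set.seed(11)
    rnd <- buildPFM(vapply(1:500, function(i)
        paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = ""),
        character(1)))
    expect_true(all(colSums(rnd$freq) == 1))
    expect_true(all(rnd$info >= 0 & rnd$info <= 2))
})

test_that("planted motif columns carry the binomial-expected frequency", {
    set.seed(4)
    n <- 10000L
    planted <- runif(n) < 0.7
    inside <- ifelse(planted, "TAT",
        vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""),
            character(1)))
    windows <- paste0("CCCCC", inside, "GG")   # wOut = 5, wIn = 5
    pfm <- buildPFM(windows)
    expected <- 0.7 + 0.3 * 0.25
    for (j in 6:8)
        expect_lt(abs(max(pfm$freq[, j]) - expected), 0.02)
})

test_that("top k-mer recovery flags mirror palindromes", {
    set.seed(4)
    n <- 10000L
    planted <- runif(n) < 0.7
    inside <- ifelse(planted, "TAT",
        vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""),
            character(1)))
    fl <- list(fivePrime = paste0("CCCCC", inside, "GG"), wOut = 5L,
               wIn = 5L)
    tk <- topKmer(fl)
    expect_equal(tk$kmer, "TAT")
    expect_lt(abs(tk$frequency - (0.7 + 0.3 / 64)), 0.02)
    expect_true(tk$mirrorPalindromic)

    # uniform random termini sit at the multinomial background
    set.seed(5)
    rndIn <- vapply(seq_len(20000L), function(i)
        paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""),
        character(1))
    tkR <- topKmer(list(fivePrime = paste0("CCCCC", rndIn, "GG"),
                        wOut = 5L, wIn = 5L))
    expect_lt(tkR$frequency, 1 / 64 + 4 * sqrt((1 / 64) / 20000L))

    tk1 <- topKmer(list(fivePrime = rep("CCCCCAAAAA", 5L), wOut = 5L,
                        wIn = 5L), k = 1L)
    expect_equal(tk1$kmer, "A")
    expect_equal(tk1$frequency, 1)
    expect_true(tk1$mirrorPalindromic)
})

test_that("the proliferative scenario's planted motif is recovered and
           absent elsewhere", {
    ref <- refFixture()
    cfg <- scenarioConfig("proliferative", nFragments = 30000L,
                          seed = 23L)
    s <- sampleFragments(cfg, ref)
    cls <- classifyFragments(s$fragments)
    tk <- topKmer(extractFlanks(ref, cls$nfr))
    expect_equal(tk$kmer, "TAT")
    expect_true(tk$mirrorPalindromic)
    expect_gt(tk$frequency, 0.4)
    # fragments flagged as planted carry the motif on the reference
    truth <- s$truth
    pl <- truth[truth$motifPlanted == TRUE, ]
    idx <- match(pl$id, S4Vectors::mcols(fragments(s$fragments))$id)
    flP <- extractFlanks(ref, methods::new("FragmentSet",
        fragments = fragments(s$fragments)[idx], mitoContig = "chrM"))
    expect_true(all(substr(flP$fivePrime, 6L, 8L) == "TAT"))

    # apoptotic scenario: background-level top k-mer
    sA <- sampleFragments(scenarioConfig("apoptotic",
        nFragments = 30000L, seed = 23L), ref)
    tkA <- topKmer(extractFlanks(ref, sA$fragments))
    expect_lt(tkA$frequency, 0.05)
})
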