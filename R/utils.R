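# shared helpers

# centered moving average; ends are padded by shrinking the window
.movingAverage <- function(x, window) {
    if (window <= 1L) return(x)
    n <- length(x)
    cs <- cumsum(c(0, x))
    half <- window %/% 2L
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# per-stage seeds derived from one run seed; kept < 2^31
.deriveSeed <- function(seed, stage) {
    as.integer((as.numeric(seed) * 1000 + stage) %% .Machine$integer.max)
}

.stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)

# empty fragment GRanges with the FragmentSet metadata schema
.emptyFragmentGR <- function(seqlengths = NULL) {
    gr <- .mkGRanges(character(), integer(), integer(),
                     seqlengths = seqlengths)
    GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(id = character(),
        size = integer(), sizeSource = character(), mapq = integer(),
        origin = character())
    gr
}

# GRanges from contig / 1-based start,end vectors with common checks
.mkGRanges <- function(contig, start, end, strand = "*", seqlengths = NULL) {
    GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                           strand = rep(strand, length.out = length(start)),
                           seqlengths = seqlengths)
}
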