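#' Randomly sample fragments for terminus analysis
#'
#' Uniform sampling without replacement; the default draw of 5,000,000
#' matches the depth-normalization used for end-motif construction. When
#' fewer fragments are available, all are taken with a warning.
#'
#' @param x a \code{\link{FragmentSet}} (typically one NFR or NBR class).
#' @param n number of fragments to draw (default 5e6).
#' @param seed RNG seed for reproducible sampling.
#' @return a \code{FragmentSet} with the sampled fragments.
#' @export
sampleTermini <- function(x, n = 5000000L, seed = 1L) {
    set.seed(seed)
    avail <- length(x)
    if (avail < n) {
        warning("only ", avail, " fragments available; taking all")
        n <- avail
    }
    idx <- sample.int(avail, n)
    methods::initialize(x, fragments = fragments(x)[idx])
}

# clamped, N-padded reference slice (vectorized over equal-width windows)
.paddedSlice <- function(chrSeq, start, end) {
    L <- length(chrSeq)
    cs <- pmax(start, 1L); ce <- pmin(end, L)
    core <- character(length(start))
    nonEmpty <- cs <= ce
    if (any(nonEmpty))
        core[nonEmpty] <- as.character(extractAt(chrSeq,
            IRanges::IRanges(cs[nonEmpty], ce[nonEmpty])))
    paste0(strrep("N", pmax(0L, 1L - start)), core,
           strrep("N", pmax(0L, end - L)))
}

#' Extract breakpoint-spanning sequences at fragment termini
#'
#' For each fragment the 5' and 3' breakpoints are flanked by
#' \code{wOut} reference bases outside the fragment and \code{wIn} bases
#' inside it; windows are oriented in the fragment's read direction
#' (reverse-complemented for minus-orientation fragments, with the 5'/3'
#' roles swapped accordingly) and N-padded at contig edges. Reference
#' sequence is used for both sides so the outside context is available;
#' inside, read and reference agree for error-free fragments.
#'
#' @param reference result of \code{\link{buildReference}} (or any list
#'   with a \code{genome} DNAStringSet).
#' @param x a \code{\link{FragmentSet}} or GRanges with strand.
#' @param wOut,wIn window widths outside/inside the breakpoint (bp).
#' @return list with \code{fivePrime} and \code{threePrime}
#'   character vectors of width \code{wOut + wIn} (5': outside then
#'   inside; 3': inside then outside), plus \code{wOut}, \code{wIn}.
#' @export
extractFlanks <- function(reference, x, wOut = 5L, wIn = 5L) {
    gr <- if (is(x, "FragmentSet")) fragments(x) else x
    ct <- as.character(seqnames(gr))
    s <- start(gr); e <- end(gr)
    neg <- as.character(strand(gr)) == "-"
    five <- character(length(gr)); three <- character(length(gr))
    for (c1 in unique(ct)) {
        i <- ct == c1
        chrSeq <- reference$genome[[c1]]
        # plus orientation: 5' window [s-wOut, s+wIn-1], 3' [e-wIn+1, e+wOut]
        leftWin <- .paddedSlice(chrSeq, s[i] - wOut, s[i] + wIn - 1L)
        rightWin <- .paddedSlice(chrSeq, e[i] - wIn + 1L, e[i] + wOut)
        ip <- i & !neg; im <- i & neg
        five[ip] <- leftWin[!neg[i]]
        three[ip] <- rightWin[!neg[i]]
        # minus orientation: roles swap and windows reverse-complement
        five[im] <- .revcomp(rightWin[neg[i]])
        three[im] <- .revcomp(leftWin[neg[i]])
    }
    list(fivePrime = five, threePrime = three, wOut = wOut, wIn = wIn)
}

#' Position frequency matrix with information content
#'
#' Per-position base counts over A,C,G,T for a set of equal-width
#' terminus windows; N bases are excluded from their column's total.
#' Information content per column is \code{2 + sum(f * log2(f))} bits,
#' bounded in [0, 2].
#'
#' @param windows character vector (or DNAStringSet) of equal-width
#'   sequences.
#' @return list with \code{counts} (4 x width matrix), \code{freq}
#'   (column-normalized), \code{info} (bits per column),
#'   \code{colTotals}.
#' @export
buildPFM <- function(windows) {
    .stopIfNot(length(windows) >= 1, "at least one window is required")
    xs <- Biostrings::DNAStringSet(windows)
    cm <- Biostrings::consensusMatrix(xs)
    bases <- c("A", "C", "G", "T")
    counts <- matrix(0, 4, Biostrings::width(xs)[1],
                     dimnames = list(bases, NULL))
    present <- intersect(bases, rownames(cm))
    counts[present, ] <- cm[present, , drop = FALSE]
    colTotals <- colSums(counts)
    freq <- sweep(counts, 2, pmax(colTotals, 1), "/")
    info <- apply(freq, 2, function(f) {
        f <- f[f > 0]
        if (!length(f)) return(0)
        2 + sum(f * log2(f))
    })
    info[colTotals == 0] <- 0
    list(counts = counts, freq = freq, info = info, colTotals = colTotals)
}

#' Most frequent k-mer at the inside edge of 5' terminus windows
#'
#' Counts the k-mer at inside offsets 1..k of each 5' window (the first
#' k fragment bases) and reports the winner, its frequency, and whether
#' it is mirror-palindromic (equal to its own reversal; for odd k,
#' reverse-complement palindromes cannot exist, so mirror symmetry is the
#' operative reading of "palindromic").
#'
#' @param flanks result of \code{\link{extractFlanks}}.
#' @param k k-mer length (default 3).
#' @return list(kmer, frequency, mirrorPalindromic, n).
#' @export
topKmer <- function(flanks, k = 3L) {
    kmers <- substr(flanks$fivePrime, flanks$wOut + 1L, flanks$wOut + k)
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    .stopIfNot(length(kmers) > 0, "no N-free terminus k-mers")
    tab <- sort(table(kmers), decreasing = TRUE)
    kmer <- names(tab)[1]
    rev_k <- paste(rev(strsplit(kmer, "")[[1]]), collapse = "")
    list(kmer = kmer, frequency = as.numeric(tab[1]) / length(kmers),
         mirrorPalindromic = kmer == rev_k, n = length(kmers))
}

#' Write a PFM as TSV (position, A, C, G, T, info_bits)
#' @param pfm result of \code{\link{buildPFM}}.
#' @param path output path.
#' @export
writePFM <- function(pfm, path) {
    data.table::fwrite(data.table::data.table(
        position = seq_len(ncol(pfm$counts)),
        A = pfm$counts["A", ], C = pfm$counts["C", ],
        G = pfm$counts["G", ], T = pfm$counts["T", ],
        info_bits = pfm$info), path, sep = "\t")
    invisible(path)
}
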