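#' Read a SAM (text dialect) file into an alignment table
#'
#' Parses the mandatory 11 SAM columns plus the \code{SA:Z} supplementary
#' alignment tag into a \code{data.table}, one row per alignment record, in
#' file order. Positions are kept 1-based as in SAM. Flag bits are unpacked
#' into \code{isRead1}, \code{isRead2}, \code{isReverse},
#' \code{isSupplementary} and \code{isPaired}.
#'
#' @param path path to a SAM text file. The header must declare every
#'   contig used by a record (\code{@SQ} lines); a record naming an
#'   undeclared contig is a hard error.
#' @return a \code{data.table} with columns \code{qname, flag, contig, pos,
#'   mapq, cigar, rnext, pnext, tlen, seq, sa} plus the unpacked flag
#'   logicals, and attributes \code{seqlengths} (named integer vector from
#'   the header).
#' @export
readAlignments <- function(path) {
    .stopIfNot(file.exists(path), paste("no such file:", path))
    lines <- readLines(path)
    isHeader <- startsWith(lines, "@")
    header <- lines[isHeader]
    body <- lines[!isHeader]
    sq <- header[startsWith(header, "@SQ")]
    .stopIfNot(length(header) > 0 && length(sq) > 0,
               "SAM header with @SQ lines is required")
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seqlengths <- stats::setNames(ln, sn)
    if (length(body) == 0) {
        out <- data.table::data.table(qname = character(), flag = integer(),
            contig = character(), pos = integer(), mapq = integer(),
            cigar = character(), rnext = character(), pnext = integer(),
            tlen = integer(), seq = character(), sa = character(),
            isPaired = logical(), isRead1 = logical(), isRead2 = logical(),
            isReverse = logical(), isSupplementary = logical())
        data.table::setattr(out, "seqlengths", seqlengths)
        return(out)
    }
    nf <- lengths(gregexpr("\t", body, fixed = TRUE)) + 1L
    bad <- which(nf < 11L)
    if (length(bad))
        stop("malformed SAM record(s) (fewer than 11 fields) at line(s): ",
             paste(utils::head(which(!isHeader)[bad], 10), collapse = ", "))
    dt <- data.table::fread(text = body, sep = "\t", header = FALSE,
                            fill = Inf, colClasses = "character")
    out <- data.table::data.table(
        qname = dt[[1]], flag = as.integer(dt[[2]]), contig = dt[[3]],
        pos = as.integer(dt[[4]]), mapq = as.integer(dt[[5]]),
        cigar = dt[[6]], rnext = dt[[7]], pnext = as.integer(dt[[8]]),
        tlen = as.integer(dt[[9]]), seq = dt[[10]])
    # optional fields: keep the SA tag only
    sa <- rep(NA_character_, nrow(out))
    if (ncol(dt) > 11L) {
        for (j in 12:ncol(dt)) {
            v <- dt[[j]]
            hit <- !is.na(v) & startsWith(v, "SA:Z:")
            sa[hit] <- substring(v[hit], 6L)
        }
    }
    out$sa <- sa
    out$isPaired <- bitwAnd(out$flag, 1L) > 0L
    out$isRead1 <- bitwAnd(out$flag, 64L) > 0L
    out$isRead2 <- bitwAnd(out$flag, 128L) > 0L
    out$isReverse <- bitwAnd(out$flag, 16L) > 0L
    out$isSupplementary <- bitwAnd(out$flag, 2048L) > 0L
    mapped <- out$contig != "*"
    unknown <- unique(out$contig[mapped & !(out$contig %in% sn)])
    if (length(unknown))
        stop("record(s) on contig(s) absent from header: ",
             paste(unknown, collapse = ", "))
    data.table::setattr(out, "seqlengths", seqlengths)
    out
}

#' Parse an SA:Z supplementary-alignment tag
#'
#' @param sa the tag payload (semicolon-separated
#'   \code{rname,pos,strand,CIGAR,mapQ,NM;} entries), or \code{NA}.
#' @return data.frame with columns \code{contig, pos, strand, cigar}
#'   (zero rows for \code{NA}/empty input).
#' @export
parseSATag <- function(sa) {
    if (length(sa) != 1L || is.na(sa) || !nzchar(sa))
        return(data.frame(contig = character(), pos = integer(),
                          strand = character(), cigar = character()))
    parts <- strsplit(strsplit(sa, ";", fixed = TRUE)[[1]], ",",
                      fixed = TRUE)
    data.frame(
        contig = vapply(parts, `[`, "", 1L),
        pos = as.integer(vapply(parts, `[`, "", 2L)),
        strand = vapply(parts, `[`, "", 3L),
        cigar = vapply(parts, `[`, "", 4L))
}

# reference-consumed width of CIGAR strings (vectorized, fast path for xM)
.cigarRefWidth <- function(cigar) {
    out <- integer(length(cigar))
    plain <- grepl("^[0-9]+M$", cigar)
    out[plain] <- as.integer(sub("M", "", cigar[plain], fixed = TRUE))
    rest <- which(!plain)
    if (length(rest)) {
        chunks <- regmatches(cigar[rest],
                             gregexpr("[0-9]+[MIDNSHP=X]", cigar[rest]))
        out[rest] <- vapply(chunks, function(ch) {
            op <- substring(ch, nchar(ch))
            sum(as.integer(substring(ch, 1L, nchar(ch) - 1L))[
                op %in% c("M", "D", "N", "=", "X")])
        }, integer(1))
    }
    out
}

# query-consumed width (M,I,S,=,X)
.cigarQueryWidth <- function(cigar) {
    chunks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
    vapply(chunks, function(ch) {
        op <- substring(ch, nchar(ch))
        sum(as.integer(substring(ch, 1L, nchar(ch) - 1L))[
            op %in% c("M", "I", "S", "=", "X")])
    }, integer(1))
}

#' Reconstruct one fragment from a concordant read pair
#'
#' The fragment interval spans from the leftmost mate start to the
#' rightmost aligned mate end. Discordant pairs (mates on different
#' contigs, TLEN of 0, or both mates in the same orientation) return
#' \code{NULL}; these are dropped, not repaired.
#'
#' @param r1,r2 single-row alignment records (as from
#'   \code{\link{readAlignments}}) sharing a query name, neither
#'   supplementary.
#' @param mitoContig contig name whose fragments are mitochondrial.
#' @param readLength sequencing read length; read-1 sequences shorter than
#'   this carry the fragment size directly (hybrid size metric).
#' @return one-row data.frame (contig, start, end, size, sizeSource, mapq,
#'   origin, strand) or \code{NULL} for a discordant or unsizeable pair.
#' @export
pairToFragment <- function(r1, r2, mitoContig = "chrM", readLength = 150L) {
    .stopIfNot(r1$qname == r2$qname, "mates must share a query name")
    .stopIfNot(!r1$isSupplementary && !r2$isSupplementary,
               "supplementary records cannot form a fragment")
    if (r1$contig != r2$contig) return(NULL)
    if (r1$isReverse == r2$isReverse) return(NULL)
    if (r1$tlen == 0L) return(NULL)
    a <- if (r1$isRead1) r1 else r2
    b <- if (r1$isRead1) r2 else r1
    hs <- hybridSize(nchar(a$seq), a$tlen, readLength)
    if (is.null(hs)) return(NULL)
    start <- min(r1$pos, r2$pos)
    end <- max(r1$pos + .cigarRefWidth(r1$cigar),
               r2$pos + .cigarRefWidth(r2$cigar)) - 1L
    data.frame(contig = r1$contig, start = start, end = end,
               size = hs$size, sizeSource = hs$source,
               mapq = min(r1$mapq, r2$mapq),
               origin = if (r1$contig == mitoContig) "mito" else "nuclear",
               strand = if (a$isReverse) "-" else "+")
}

#' Reconstruct all fragments from an alignment table
#'
#' Vectorized pairing of primary read-1/read-2 records by query name,
#' applying the hybrid size metric (read length below \code{readLength},
#' insert size at or above it). Discordant pairs and pairs whose size is
#' unknowable (TLEN 0 at full read length) are dropped with a message.
#'
#' @param aln alignment table from \code{\link{readAlignments}}.
#' @param mitoContig mitochondrial contig name.
#' @param readLength sequencing read length (bp).
#' @return a \code{\link{FragmentSet}}.
#' @export
pairFragments <- function(aln, mitoContig = "chrM", readLength = 150L) {
    seqlengths <- attr(aln, "seqlengths")
    prim <- aln[!aln$isSupplementary & aln$isPaired &
                bitwAnd(aln$flag, 256L) == 0L, ]
    r1 <- prim[prim$isRead1, ]
    r2 <- prim[prim$isRead2, ]
    data.table::setkey(r1, qname)
    data.table::setkey(r2, qname)
    m <- r2[r1, nomatch = 0L]   # columns of r2, i.* = r1
    if (nrow(m) == 0L)
        return(new("FragmentSet",
                   fragments = .emptyFragmentGR(seqlengths),
                   mitoContig = mitoContig))
    concordant <- m$contig == m$i.contig & (m$isReverse != m$i.isReverse) &
        m$i.tlen != 0L
    r1len <- nchar(m$i.seq)
    useRead <- r1len < readLength
    size <- ifelse(useRead, r1len, abs(m$i.tlen))
    sizeable <- useRead | m$i.tlen != 0L
    keep <- concordant & sizeable
    nd <- sum(!keep)
    if (nd) message(nd, " discordant/unsizeable pair(s) dropped")
    m <- m[keep, ]
    size <- size[keep]
    src <- ifelse(useRead[keep], "read_length", "insert_size")
    start <- pmin(m$pos, m$i.pos)
    end <- pmax(m$pos + .cigarRefWidth(m$cigar),
                m$i.pos + .cigarRefWidth(m$i.cigar)) - 1L
    gr <- .mkGRanges(m$contig, start, end,
                     strand = ifelse(m$i.isReverse, "-", "+"),
                     seqlengths = seqlengths)
    mcols(gr) <- DataFrame(id = m$qname, size = as.integer(size),
        sizeSource = src, mapq = pmin(m$mapq, m$i.mapq),
        origin = ifelse(m$contig == mitoContig, "mito", "nuclear"))
    new("FragmentSet", fragments = gr, mitoContig = mitoContig)
}

#' Read a BED3/BED6 file into a GRanges
#'
#' BED half-open 0-based intervals become 1-based closed GRanges. Strand
#' defaults to "*" when absent or ".".
#'
#' @param path BED file path.
#' @return GRanges (with \code{name} and \code{score} mcols when present),
#'   sorted per contig.
#' @export
readBed <- function(path) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    strand <- if (ncol(dt) >= 6) ifelse(dt[[6]] == ".", "*", dt[[6]]) else "*"
    gr <- .mkGRanges(as.character(dt[[1]]), dt[[2]] + 1L, dt[[3]],
                     strand = strand)
    if (ncol(dt) >= 4) mcols(gr)$name <- as.character(dt[[4]])
    if (ncol(dt) >= 5) mcols(gr)$score <- dt[[5]]
    sort(gr)
}

#' Write a GRanges as BED6
#'
#' @param gr GRanges; \code{name}/\code{score} mcols are used when present.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else "."
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    st <- as.character(strand(gr))
    st[st == "*"] <- "."
    dt <- data.table::data.table(as.character(seqnames(gr)),
        start(gr) - 1L, end(gr), nm, sc, st)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read a RepeatMasker-like repeat table
#'
#' Tab-separated with header columns
#' \code{contig,start,end,repName,repClass,repFamily}; start is 0-based
#' half-open as in BED.
#'
#' @param path file path.
#' @return GRanges with mcols repName, repClass, repFamily, sorted.
#' @export
readRepeatTable <- function(path) {
    dt <- data.table::fread(path, header = TRUE, sep = "\t")
    gr <- .mkGRanges(as.character(dt$contig), dt$start + 1L, dt$end)
    mcols(gr)$repName <- as.character(dt$repName)
    mcols(gr)$repClass <- as.character(dt$repClass)
    mcols(gr)$repFamily <- as.character(dt$repFamily)
    sort(gr)
}

#' Write a RepeatMasker-like repeat table
#' @param gr GRanges with mcols repName, repClass, repFamily.
#' @param path output path.
#' @export
writeRepeatTable <- function(gr, path) {
    dt <- data.table::data.table(contig = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr),
        repName = mcols(gr)$repName, repClass = mcols(gr)$repClass,
        repFamily = mcols(gr)$repFamily)
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Filter fragments by blacklist overlap and mapping quality
#'
#' Removes any fragment overlapping a blacklist interval by at least 1 bp,
#' or with MAPQ below \code{mapqMin}. Order is preserved and the operation
#' is idempotent.
#'
#' @param x a \code{\link{FragmentSet}}.
#' @param blacklist GRanges of excluded regions (may be empty).
#' @param mapqMin minimum fragment MAPQ kept (fragment MAPQ is the minimum
#'   of its mates).
#' @return filtered \code{FragmentSet}; removal counts are messaged.
#' @export
filterFragments <- function(x, blacklist = GenomicRanges::GRanges(),
                            mapqMin = 0L) {
    .stopIfNot(mapqMin >= 0L, "mapqMin must be >= 0")
    gr <- fragments(x)
    hitBl <- IRanges::overlapsAny(gr, blacklist, ignore.strand = TRUE)
    lowQ <- mcols(gr)$mapq < mapqMin
    drop <- hitBl | lowQ
    message(sum(hitBl), " fragment(s) removed by blacklist, ",
            sum(lowQ & !hitBl), " additional by MAPQ < ", mapqMin)
    methods::initialize(x, fragments = gr[!drop])
}
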