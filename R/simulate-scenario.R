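#' Circle specification constructor
#'
#' @param sizeClass "micro" (< 1 kb) or "long" (>= 1 kb).
#' @param sizePeaks two-column matrix of (bp, sd) Gaussian size
#'   components; micro default \code{rbind(c(202, 3), c(349, 3))}, the
#'   characteristic microDNA size peaks.
#' @param sizeWeights component mixing weights; the default 0.6/0.4 makes
#'   the first (202 bp) component dominant, as in published microDNA
#'   length spectra.
#' @param count number of circles.
#' @param readsPerCircle mean junction-read support (Poisson).
#' @param junctionRepeatLen direct-repeat length planted at both junction
#'   flanks (bp).
#' @return a \code{\link{CircleSpec-class}} object.
#' @export
circleSpec <- function(sizeClass = "micro",
                       sizePeaks = if (sizeClass == "micro")
                           rbind(c(202, 3), c(349, 3))
                       else rbind(c(2000, 100)),
                       sizeWeights = if (nrow(sizePeaks) == 2) c(0.6, 0.4)
                       else rep(1, nrow(sizePeaks)),
                       count = 200L, readsPerCircle = 5,
                       junctionRepeatLen = 4L) {
    new("CircleSpec", sizeClass = sizeClass, sizePeaks = sizePeaks,
        sizeWeights = sizeWeights, count = as.integer(count),
        readsPerCircle = readsPerCircle,
        junctionRepeatLen = as.integer(junctionRepeatLen))
}

#' Scenario configuration constructor
#'
#' Builds the parameter set of one synthetic cfDNA scenario. Per-scenario
#' defaults:
#' \describe{
#'   \item{plasma_like}{167 bp mononucleosomal mode, 2 percent
#'     mitochondrial fragments, a 53 bp single-stranded-library minor peak
#'     carrying 5 percent of fragments.}
#'   \item{proliferative}{155 bp mode, 45 percent short-fragment component
#'     (piecewise exponential with a slope change at 118 bp), a 3 bp motif
#'     planted at short-fragment 5' termini with probability 0.7, and
#'     short-fragment end placement biased into Simple_repeat/Satellite
#'     intervals.}
#'   \item{apoptotic}{155 bp mode (145 bp variant selectable via
#'     \code{nucleosomeMode}), plasma-like shape with only 5 percent short
#'     fragments.}
#' }
#'
#' @param name one of "plasma_like", "proliferative", "apoptotic".
#' @param nFragments fragments to draw.
#' @param seed RNG seed; a fixed seed gives byte-identical outputs.
#' @param nucleosomeMode mononucleosomal mode (bp).
#' @param ladderPeriod nucleosomal ladder period (bp, default 10).
#' @param ladderDecay geometric weight per ladder step (default 0.6).
#' @param peakSd Gaussian jitter sd around ladder peaks (bp).
#' @param shortWeight fraction of fragments in the short component.
#' @param shortMinorPeak location of the plasma-like short minor peak (bp).
#' @param shortMinorScale Laplace scale of that minor peak (bp).
#' @param shortKink slope-change size of the piecewise-exponential short
#'   component (bp).
#' @param shortDecayPre,shortDecayPost exponential rates before/after the
#'   kink (\code{shortDecayPost} must exceed \code{shortDecayPre}).
#' @param shortMin,shortMax support of the short component (bp).
#' @param mitoFraction fraction of mitochondrial fragments (uniform
#'   30-100 bp, no periodicity).
#' @param plantedEndMotif 3-mer planted at short-fragment 5' termini
#'   (proliferative only; a mirror-symmetric stand-in, default "TAT").
#' @param motifPlantProb planting probability (default 0.7).
#' @param repeatEndBias named numeric, repClass to relative end-placement
#'   weight for short-component fragments.
#' @param circles list of \code{\link{circleSpec}} objects.
#' @param readLength platform read length (bp, default 150).
#' @param lowMapqFrac,lowMapq fraction of fragments emitted at the reduced
#'   MAPQ value.
#' @return a \code{\link{ScenarioConfig-class}} object.
#' @export
scenarioConfig <- function(name = c("plasma_like", "proliferative",
                                    "apoptotic"),
    nFragments = 200000L, seed = 42L,
    nucleosomeMode = switch(name, plasma_like = 167L, 155L),
    ladderPeriod = 10L, ladderDecay = 0.6, peakSd = 1.5,
    shortWeight = switch(name, proliferative = 0.45, 0.05),
    shortMinorPeak = 53L, shortMinorScale = 5,
    shortKink = 118L, shortDecayPre = 0.010, shortDecayPost = 0.055,
    shortMin = 30L, shortMax = 400L,
    mitoFraction = switch(name, plasma_like = 0.02, 0),
    plantedEndMotif = switch(name, proliferative = "TAT", ""),
    motifPlantProb = 0.7,
    repeatEndBias = switch(name,
        proliferative = c(Simple_repeat = 4, Satellite = 4),
        stats::setNames(numeric(), character())),
    circles = list(), readLength = 150L,
    lowMapqFrac = 0.02, lowMapq = 20L) {
    name <- match.arg(name)
    new("ScenarioConfig", name = name, nFragments = as.integer(nFragments),
        seed = as.integer(seed),
        nucleosomeMode = as.integer(nucleosomeMode),
        ladderPeriod = as.integer(ladderPeriod),
        ladderDecay = ladderDecay, peakSd = peakSd,
        shortWeight = shortWeight,
        shortMinorPeak = as.integer(shortMinorPeak),
        shortMinorScale = shortMinorScale,
        shortKink = as.integer(shortKink),
        shortDecayPre = shortDecayPre, shortDecayPost = shortDecayPost,
        shortMin = as.integer(shortMin), shortMax = as.integer(shortMax),
        mitoFraction = mitoFraction, plantedEndMotif = plantedEndMotif,
        motifPlantProb = motifPlantProb, repeatEndBias = repeatEndBias,
        circles = circles, readLength = as.integer(readLength),
        lowMapqFrac = lowMapqFrac, lowMapq = as.integer(lowMapq))
}

# piecewise-exponential sampler (inverse CDF): rate a1 on [lo, kink],
# a2 on (kink, hi]
.rPiecewiseExp <- function(n, a1, a2, lo, kink, hi) {
    m1 <- (1 - exp(-a1 * (kink - lo))) / a1
    c2 <- exp(-a1 * (kink - lo))
    m2 <- c2 * (1 - exp(-a2 * (hi - kink))) / a2
    u <- stats::runif(n) * (m1 + m2)
    ifelse(u < m1,
           lo - log(1 - a1 * u) / a1,
           kink - log(1 - a2 * (u - m1) / c2) / a2)
}

# analytic mass of the short component at or below a size cutoff
.shortMassBelow <- function(config, cutoff) {
    a1 <- config@shortDecayPre; a2 <- config@shortDecayPost
    lo <- config@shortMin; kink <- config@shortKink; hi <- config@shortMax
    m1 <- (1 - exp(-a1 * (kink - lo))) / a1
    c2 <- exp(-a1 * (kink - lo))
    m2 <- c2 * (1 - exp(-a2 * (hi - kink))) / a2
    below <- if (cutoff <= kink) (1 - exp(-a1 * (cutoff - lo))) / a1
             else m1 + c2 * (1 - exp(-a2 * (cutoff - kink))) / a2
    below / (m1 + m2)
}

#' Analytic fraction of fragments at or below a size under a scenario
#'
#' Closed-form mass of the configured size mixture at or below
#' \code{cutoff} bp (ladder component via the Gaussian CDF per peak, short
#' component via the piecewise-exponential or Laplace integral, mito
#' component via the uniform CDF). Used to check simulated samples against
#' their own generating mixture.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param cutoff size cutoff in bp.
#' @return expected fraction in [0, 1].
#' @export
expectedMassBelow <- function(config, cutoff) {
    wMito <- config@mitoFraction
    wShort <- config@shortWeight
    wLad <- 1 - wMito - wShort
    kw <- config@ladderDecay^(0:6)
    kw <- kw / sum(kw)
    ladMass <- sum(kw * stats::pnorm(cutoff + 0.5,
        config@nucleosomeMode - (0:6) * config@ladderPeriod, config@peakSd))
    shortMass <- if (config@name == "plasma_like") {
        b <- config@shortMinorScale; m <- config@shortMinorPeak
        if (cutoff < m) 0.5 * exp((cutoff - m) / b)
        else 1 - 0.5 * exp(-(cutoff - m) / b)
    } else .shortMassBelow(config, cutoff)
    mitoMass <- max(0, min(1, (cutoff - 30 + 1) / (100 - 30 + 1)))
    wLad * ladMass + wShort * shortMass + wMito * mitoMass
}

# snap positions to the nearest element of a sorted vector
.snapToNearest <- function(pos, sorted) {
    if (!length(sorted)) return(pos)
    i <- findInterval(pos, sorted)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(sorted))
    dLo <- abs(pos - sorted[lo])
    dHi <- abs(pos - sorted[hi])
    ifelse(dLo <= dHi, sorted[lo], sorted[hi])
}

#' Sample a cfDNA fragment population for a scenario
#'
#' Draws fragment sizes from the scenario mixture (nucleosomal ladder with
#' geometric peak weights and Gaussian jitter; short component:
#' piecewise-exponential with a slope change at the kink, or a Laplace
#' minor peak for plasma_like; mitochondrial component: uniform 30-100 bp
#' without oscillation), places fragments uniformly on the nuclear contig
#' except that short-component 5' ends are re-weighted into repeat
#' intervals per \code{repeatEndBias}, and (proliferative scenario) snaps
#' short fragments so the reference 3-mer at the 5' terminus equals the
#' planted motif with the configured probability.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param reference result of \code{\link{buildReference}} (possibly with
#'   planted circles).
#' @return list with \code{fragments} (a \code{\link{FragmentSet}}) and
#'   \code{truth} (data.table: id, contig, start0, end0 in 0-based
#'   half-open coordinates, size, component, orientation, motifPlanted,
#'   mapq).
#' @export
sampleFragments <- function(config, reference) {
    set.seed(config@seed)
    n <- config@nFragments
    emptyTruth <- data.table::data.table(id = character(),
        contig = character(), start0 = integer(), end0 = integer(),
        size = integer(), component = character(), orientation = character(),
        motifPlanted = logical(), mapq = integer())
    if (n == 0L)
        return(list(fragments = new("FragmentSet",
            fragments = .emptyFragmentGR(reference$seqlengths),
            mitoContig = reference$mitoContig), truth = emptyTruth))
    probs <- c(mito = config@mitoFraction, short = config@shortWeight,
               ladder = 1 - config@mitoFraction - config@shortWeight)
    .stopIfNot(any(probs > 0), "scenario mixture is empty")
    comp <- sample(names(probs), n, replace = TRUE, prob = probs)
    nm <- sum(comp == "mito"); ns <- sum(comp == "short")
    nl <- sum(comp == "ladder")

    sizes <- integer(n)
    if (nl) {
        k <- sample(0:6, nl, replace = TRUE, prob = config@ladderDecay^(0:6))
        sizes[comp == "ladder"] <- pmax(30L, as.integer(round(
            stats::rnorm(nl, config@nucleosomeMode - k * config@ladderPeriod,
                         config@peakSd))))
    }
    if (ns) {
        s <- if (config@name == "plasma_like") {
            sgn <- sample(c(-1, 1), ns, replace = TRUE)
            config@shortMinorPeak +
                sgn * stats::rexp(ns, 1 / config@shortMinorScale)
        } else .rPiecewiseExp(ns, config@shortDecayPre,
            config@shortDecayPost, config@shortMin, config@shortKink,
            config@shortMax)
        sizes[comp == "short"] <- pmax(20L, as.integer(round(s)))
    }
    if (nm) sizes[comp == "mito"] <- sample(30:100, nm, replace = TRUE)

    orient <- sample(c("+", "-"), n, replace = TRUE)
    contigs <- names(reference$seqlengths)
    nucContig <- setdiff(contigs, reference$mitoContig)[1]
    nucLen <- reference$seqlengths[[nucContig]]
    mitoLen <- reference$seqlengths[[reference$mitoContig]]
    margin <- 200L

    start <- integer(n)
    contig <- ifelse(comp == "mito", reference$mitoContig, nucContig)
    isMito <- comp == "mito"
    if (nm)
        start[isMito] <- sample.int(mitoLen - 2L * margin - 100L, nm,
                                    replace = TRUE) + margin
    isNuc <- !isMito
    start[isNuc] <- sample.int(nucLen - 2L * margin - 500L, sum(isNuc),
                               replace = TRUE) + margin

    # repeat-biased 5'-end placement for short-component fragments
    bias <- config@repeatEndBias
    if (length(bias) && ns) {
        rmsk <- reference$tracks$repeats
        classBases <- vapply(names(bias), function(cl)
            sum(width(rmsk[mcols(rmsk)$repClass == cl])), numeric(1))
        pBg <- nucLen - sum(classBases)
        catProb <- c(bias * classBases, background = pBg)
        catProb <- catProb / sum(catProb)
        idxShort <- which(comp == "short")
        cat5 <- sample(names(catProb), length(idxShort), replace = TRUE,
                       prob = catProb)
        for (cl in names(bias)) {
            sel <- idxShort[cat5 == cl]
            if (!length(sel)) next
            ivs <- rmsk[mcols(rmsk)$repClass == cl]
            iv <- sample(seq_along(ivs), length(sel), replace = TRUE,
                         prob = width(ivs))
            p5 <- start(ivs)[iv] +
                as.integer(floor(stats::runif(length(sel)) * width(ivs)[iv]))
            # 5' end is the left end for "+", the right end for "-"
            newStart <- ifelse(orient[sel] == "+", p5, p5 - sizes[sel] + 1L)
            start[sel] <- as.integer(pmin(pmax(newStart, margin),
                                          nucLen - margin - sizes[sel]))
        }
    }

    # plant the 5'-terminal motif by snapping fragments onto reference
    # positions that already carry it (read and reference stay identical)
    motifPlanted <- logical(n)
    if (nzchar(config@plantedEndMotif) && ns) {
        motif <- config@plantedEndMotif
        chrSeq <- reference$genome[[nucContig]]
        plusPos <- sort(start(matchPattern(motif, chrSeq)))
        minusPos <- sort(end(matchPattern(
            as.character(reverseComplement(DNAString(motif))), chrSeq)))
        idxShort <- which(comp == "short")
        doPlant <- stats::runif(length(idxShort)) < config@motifPlantProb
        sel <- idxShort[doPlant]
        if (length(sel)) {
            plus <- orient[sel] == "+"
            cur5 <- ifelse(plus, start[sel], start[sel] + sizes[sel] - 1L)
            new5 <- cur5
            new5[plus] <- .snapToNearest(cur5[plus], plusPos)
            new5[!plus] <- .snapToNearest(cur5[!plus], minusPos)
            newStart <- as.integer(ifelse(plus, new5, new5 - sizes[sel] + 1L))
            ok <- newStart >= margin &
                newStart + sizes[sel] - 1L <= nucLen - margin
            start[sel[ok]] <- newStart[ok]
            motifPlanted[sel[ok]] <- TRUE
        }
    }

    end <- start + sizes - 1L
    mapq <- rep(60L, n)
    lowQ <- stats::runif(n) < config@lowMapqFrac
    mapq[lowQ] <- config@lowMapq
    ids <- sprintf("F%07d", seq_len(n))

    truth <- data.table::data.table(id = ids, contig = contig,
        start0 = start - 1L, end0 = end, size = sizes,
        component = comp, orientation = orient,
        motifPlanted = motifPlanted, mapq = mapq)
    gr <- .mkGRanges(contig, start, end, strand = orient,
                     seqlengths = reference$seqlengths)
    mcols(gr) <- DataFrame(id = ids, size = sizes,
        sizeSource = ifelse(sizes < config@readLength, "read_length",
                            "insert_size"),
        mapq = mapq, origin = ifelse(isMito, "mito", "nuclear"))
    list(fragments = new("FragmentSet", fragments = gr,
                         mitoContig = reference$mitoContig),
         truth = truth)
}
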