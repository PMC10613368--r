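#' Run the full fragmentomic pipeline on one scenario
#'
#' Orchestrates simulate, size, classify, footprint, end motif, repeat
#' attribution, circle reconstruction and statistics in dependency order,
#' writing each stage's outputs and a manifest (file list with MD5
#' checksums and all parameter values) under \code{outDir}. Per-stage
#' seeds derive from the scenario seed by a fixed rule (seed x 1000 +
#' stage index), so one number reproduces a run byte for byte.
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param outDir output directory.
#' @param nfrThreshold NFR/NBR size cutoff (bp, default 118).
#' @param mapqMin MAPQ floor for coverage (default 30).
#' @param binSize coverage bin width (bp, default 10).
#' @param endmotifN terminus sample size (default 5e6, clamped to the
#'   available fragments).
#' @param circleTol,circleMinSupport circle clustering parameters.
#' @return invisible list with the stage results and the manifest
#'   data.table.
#' @export
runPipeline <- function(config, outDir, nfrThreshold = 118L,
                        mapqMin = 30L, binSize = 10L,
                        endmotifN = 5000000L, circleTol = 5L,
                        circleMinSupport = 2L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0); stages <- character(0)
    addFile <- function(stage, path) {
        files <<- c(files, path); stages <<- c(stages, stage)
        path
    }
    logStage <- function(...) message("[pipeline] ", ...)

    # 1: simulate
    logStage("simulate: scenario ", config@name)
    simDir <- file.path(outDir, "01_simulate")
    sim <- simulateScenario(config, simDir)
    for (p in unlist(sim$paths)) addFile("simulate", p)

    # 2: read + pair + blacklist filter
    logStage("io: reading alignments")
    aln <- readAlignments(sim$paths$sam)
    frags <- pairFragments(aln, mitoContig = sim$reference$mitoContig,
                           readLength = config@readLength)
    logStage("io: ", length(frags), " fragments reconstructed")
    frags <- filterFragments(frags, sim$reference$tracks$blacklist)

    # 3: sizing
    logStage("sizing: histograms and detectors")
    sizeDir <- file.path(outDir, "03_sizing")
    dir.create(sizeDir, showWarnings = FALSE)
    profNuc <- sizeHistogram(frags, "nuclear")
    profMito <- sizeHistogram(frags, "mito")
    addFile("sizing", writeSizeProfile(profNuc,
        file.path(sizeDir, "sizes_nuclear.tsv")))
    addFile("sizing", writeSizeProfile(profMito,
        file.path(sizeDir, "sizes_mito.tsv")))
    sizing <- list(
        peaks = findSizePeaks(profNuc, 100L, 200L),
        shortPeaks = findSizePeaks(profNuc, 30L, 100L),
        period = estimatePeriodicity(profNuc),
        slopeChange = detectSlopeChange(profNuc))

    # 4: classify
    cls <- classifyFragments(frags, nfrThreshold)
    logStage("classify: ", length(cls$nfr), " NFR / ", length(cls$nbr),
             " NBR at ", nfrThreshold, " bp")
    clsDir <- file.path(outDir, "04_classify")
    dir.create(clsDir, showWarnings = FALSE)
    addFile("classify", writeBed(fragments(cls$nfr),
        file.path(clsDir, "nfr.bed")))
    addFile("classify", writeBed(fragments(cls$nbr),
        file.path(clsDir, "nbr.bed")))

    # 5: footprint
    logStage("footprint: BPM coverage and metaprofiles")
    fpDir <- file.path(outDir, "05_footprint")
    dir.create(fpDir, showWarnings = FALSE)
    footprint <- list()
    for (grp in c("nfr", "nbr")) {
        fs <- cls[[grp]]
        if (!length(fs)) next
        cov <- bpmNormalize(binnedCoverage(fs, binSize, mapqMin))
        addFile("footprint", writeBedGraph(cov,
            file.path(fpDir, paste0(grp, "_bpm.bedgraph"))))
        mp <- metaprofilePoint(cov, sim$reference$tracks$tss)
        data.table::fwrite(data.table::data.table(
            position = mp@positions, mean = meanProfile(mp)),
            addFile("footprint",
                    file.path(fpDir, paste0(grp, "_tss_profile.tsv"))),
            sep = "\t")
        footprint[[grp]] <- list(coverage = cov, tss = mp)
    }

    # 6: end motifs
    logStage("endmotif: terminus PFMs")
    emDir <- file.path(outDir, "06_endmotif")
    dir.create(emDir, showWarnings = FALSE)
    endmotif <- list()
    for (grp in c("nfr", "nbr")) {
        fs <- cls[[grp]]
        if (!length(fs)) next
        samp <- suppressWarnings(sampleTermini(fs, endmotifN,
            seed = .deriveSeed(config@seed, 6L)))
        fl <- extractFlanks(sim$reference, samp)
        pfm5 <- buildPFM(fl$fivePrime)
        addFile("endmotif", writePFM(pfm5,
            file.path(emDir, paste0(grp, "_pfm_5prime.tsv"))))
        addFile("endmotif", writePFM(buildPFM(fl$threePrime),
            file.path(emDir, paste0(grp, "_pfm_3prime.tsv"))))
        endmotif[[grp]] <- list(pfm5 = pfm5, topKmer = topKmer(fl))
    }

    # 7: repeat-end attribution
    logStage("repeats: end-position attribution")
    rpDir <- file.path(outDir, "07_repeats")
    dir.create(rpDir, showWarnings = FALSE)
    rmsk <- sim$reference$tracks$repeats
    expected <- genomeExpected(rmsk,
        sim$reference$seqlengths[setdiff(names(sim$reference$seqlengths),
                                         sim$reference$mitoContig)])
    repeats <- list(expected = expected)
    for (grp in c("nfr", "nbr")) {
        fs <- cls[[grp]]
        if (!length(fs)) next
        ann <- annotatePoints(endPositions(fs), rmsk)
        sm <- summarizeRepeatEnds(ann)
        sm$expected <- expected[sm$label]
        data.table::fwrite(sm, addFile("repeats",
            file.path(rpDir, paste0(grp, "_repeat_ends.tsv"))),
            sep = "\t")
        repeats[[grp]] <- sm
    }

    # 8: circles
    logStage("circles: junction reconstruction")
    ccDir <- file.path(outDir, "08_circles")
    dir.create(ccDir, showWarnings = FALSE)
    ev <- collectJunctions(aln)
    calls <- clusterCircleCalls(ev, tol = circleTol,
                                minSupport = circleMinSupport)
    calls <- filterTandemDuplications(calls,
        sim$reference$tracks$tandem_dups)
    circles <- list(evidence = ev, calls = calls)
    if (length(calls)) {
        circles$spectrum <- lengthSpectrum(calls)
        circles$junctions <- junctionCharacterize(calls, sim$reference,
            repeatTrack = rmsk)
        circles$cpm <- circleCPM(calls,
            nMappedReads = sum(!aln$isSupplementary))
        gr <- circleCalls(circles$junctions$calls)
        data.table::fwrite(data.table::data.table(
            contig = as.character(seqnames(gr)), start0 = start(gr) - 1L,
            end0 = end(gr), support = mcols(gr)$support,
            length = width(gr),
            microhomologyLen = mcols(gr)$microhomologyLen),
            addFile("circles", file.path(ccDir, "circle_calls.tsv")),
            sep = "\t")
    }

    manifest <- data.table::data.table(stage = stages, file = files,
        md5 = unname(tools::md5sum(files)))
    params <- data.table::data.table(
        parameter = c("scenario", "seed", "nFragments", "nfrThreshold",
                      "mapqMin", "binSize", "endmotifN", "circleTol",
                      "circleMinSupport"),
        value = as.character(c(config@name, config@seed,
            config@nFragments, nfrThreshold, mapqMin, binSize, endmotifN,
            circleTol, circleMinSupport)))
    data.table::fwrite(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t")
    data.table::fwrite(params, file.path(outDir, "parameters.tsv"),
                       sep = "\t")
    logStage("done: ", length(files), " files in manifest")
    invisible(list(fragments = frags, classification = cls,
                   sizing = sizing, footprint = footprint,
                   endmotif = endmotif, repeats = repeats,
                   circles = circles, manifest = manifest,
                   reference = sim$reference, truth = sim$truth))
}
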