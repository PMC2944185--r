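## End-to-end orchestration: simulate (or load) -> segment -> call -> MCR ->
## differential genomics -> subtype classification -> differential
## expression -> gene-set enrichment -> survival, with a JSON report.

.stageLog <- function(verbose, stage, t0) {
    if (verbose)
        message(sprintf("[%s] %s (%.1fs)", format(Sys.time(), "%H:%M:%S"),
                        stage, as.numeric(Sys.time()) - t0))
    invisible(NULL)
}

#' Run the full analysis pipeline on a (simulated) cohort
#'
#' Stages, in dependency order: cohort simulation, per-sample segmentation
#' and five-state calling, MCR derivation and differential-genomics testing
#' per event type in the chemotherapy arm (responders vs non-responders),
#' nearest-centroid subtype classification, moderated-t differential
#' expression in the radiotherapy arm with top-gene selection, fold-change
#' filtering and gene-set enrichment, and Kaplan-Meier / log-rank survival
#' comparisons. All tabular outputs are written under `outdir`; a
#' machine-readable JSON report collects the paths, summary statistics, the
#' seed and the parameter fingerprint. Identical config and seed give
#' identical outputs.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if needed).
#' @param params [callingParameters()].
#' @param minRecurrence MCR recurrence threshold.
#' @param nPerSide top genes per direction for enrichment.
#' @param verbose log stage timings to stderr.
#' @return The report, invisibly (also written to `report.json`).
#' @export
runPipeline <- function(config = simulationConfig(), outdir,
                        params = callingParameters(), minRecurrence = 2L,
                        nPerSide = 500L, verbose = TRUE) {
    stopifnot(!missing(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    t0 <- as.numeric(Sys.time())
    path <- function(f) file.path(outdir, f)
    report <- list(seed = config$seed, outputs = list(), summary = list())

    ## 1. simulate and persist inputs
    sim <- simulateCohort(config)
    writeCloneMap(cloneMap(sim$acgh), path("clone_map.tsv"))
    writeMatrixTSV(lratio(sim$acgh), path("profiles.tsv"), "clone_id")
    writeMatrixTSV(assay(sim$expression, "exprs"), path("expression.tsv"),
                   "probe_id")
    writeSampleMetadata(sim$metadata, path("metadata.tsv"))
    writeGMT(sim$geneSets, path("gene_sets.gmt"))
    .stageLog(verbose, "simulate", t0)

    ## 2. segmentation, per-sample stats, five-state calls
    ae <- segmentProfiles(sim$acgh)
    ae <- estimateProfileStats(ae, params)
    ae <- suppressWarnings(callAberrations(ae, params))
    stats <- as.data.frame(profileStats(ae))
    stats <- cbind(sample_id = rownames(stats), stats)
    write.table(stats, path("profile_stats.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeSegmentsBED(ae, path("calls.bed"))
    calls <- aberrationCalls(ae)
    report$summary$callCounts <- as.list(table(calls))
    .stageLog(verbose, "call-cgh", t0)

    ## 3. MCRs + differential genomics, chemotherapy arm
    meta <- sim$metadata
    ctSamples <- meta$sample_id[meta$treatment == "CT"]
    groupsCT <- setNames(meta$response, meta$sample_id)[ctSamples]
    diffTabs <- list()
    nMcr <- 0L
    for (event in c("homdel", "amp", "gain", "loss")) {
        mcrs <- deriveMCRs(ae, event, minRecurrence = minRecurrence,
                           samples = ctSamples)
        nMcr <- nMcr + length(mcrs)
        if (length(mcrs) == 0L) next
        diffTabs[[event]] <- differentialRegions(ae[, ctSamples], mcrs,
                                                 groupsCT, event)
    }
    diffCT <- do.call(rbind, diffTabs)
    write.table(diffCT, path("differential_regions_CT.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$summary$nMCR <- nMcr
    report$summary$nSignificantRegionsCT <-
        if (is.null(diffCT)) 0L else sum(diffCT$significant)
    top <- if (!is.null(diffCT) && nrow(diffCT) > 0L)
        diffCT[which.min(diffCT$p), ] else NULL
    if (!is.null(top))
        report$summary$topRegionCT <- list(
            chrom = top$chrom, start = top$start, end = top$end,
            event = top$event, p = top$p, q = top$q)
    .stageLog(verbose, "diff-genome", t0)

    ## 4. subtype classification (centroids from the planted labels)
    expr <- assay(sim$expression, "exprs")
    model <- buildCentroidClassifier(expr, sim$truth$classLabels)
    classes <- classifyByCentroid(model, expr)
    write.table(classes, path("subtypes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$summary$subtypeAgreement <-
        mean(classes$class == sim$truth$classLabels[classes$sample])
    .stageLog(verbose, "classify", t0)

    ## 5. differential expression, radiotherapy arm (responder = group A)
    rtSamples <- meta$sample_id[meta$treatment == "RT"]
    groupsRT <- setNames(factor(meta$response,
                                levels = c("responder", "nonresponder")),
                         meta$sample_id)[rtSamples]
    de <- moderatedTTest(expr[, rtSamples], groupsRT)
    write.table(de$table, path("de_RT.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    filt <- filterDE(de)
    report$summary$deCounts <- as.list(filt$counts)
    .stageLog(verbose, "de", t0)

    ## 6. gene-set enrichment of the top lists (probes collapse 1:1 here)
    probeGene <- setNames(rowData(sim$expression)$gene,
                          rownames(sim$expression))
    top <- suppressWarnings(selectTopGenes(de, nPerSide))
    gsc <- sim$geneSets
    enrichUp <- hypergeometricEnrichment(
        unname(probeGene[top$upInA]), gsc)
    enrichDown <- hypergeometricEnrichment(
        unname(probeGene[top$upInB]), gsc)
    write.table(enrichUp, path("enrichment_responder_up.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enrichDown, path("enrichment_nonresponder_up.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$summary$topSetResponderUp <- enrichUp$set[1L]
    report$summary$topSetNonresponderUp <- enrichDown$set[1L]
    .stageLog(verbose, "gsea", t0)

    ## 7. survival: PFS by response within each arm
    surv <- list()
    for (arm in c("RT", "CT")) {
        sub <- meta[meta$treatment == arm, ]
        lr <- logrankTest(sub$pfs_months, sub$pfs_event, sub$response)
        med <- vapply(split(sub, sub$response), function(d)
            kmEstimator(d$pfs_months, d$pfs_event)$median, numeric(1L))
        surv[[arm]] <- list(chisq = lr$chisq, p = lr$p,
                            medianPFS = as.list(med))
    }
    report$summary$survival <- surv
    .stageLog(verbose, "survival", t0)

    report$outputs <- as.list(path(c(
        "clone_map.tsv", "profiles.tsv", "expression.tsv", "metadata.tsv",
        "gene_sets.gmt", "profile_stats.tsv", "calls.bed",
        "differential_regions_CT.tsv", "subtypes.tsv", "de_RT.tsv",
        "enrichment_responder_up.tsv", "enrichment_nonresponder_up.tsv")))
    report$parameters <- list(calling = params,
                              minRecurrence = minRecurrence,
                              nPerSide = nPerSide,
                              nClones = config$nClones,
                              cells = as.list(config$cells))
    stopifnot(all(file.exists(unlist(report$outputs))))
    write_json(report, path("report.json"), auto_unbox = TRUE, digits = NA,
               pretty = TRUE)
    invisible(report)
}
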