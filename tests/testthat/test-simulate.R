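## Synthetic cohort generator: closed forms, determinism, planted structure.

test_that("noiseless profiles follow the mixture-model closed form", {
    cm <- tinyCloneMap(20, "chr7")
    ## no events: everything at exactly 0
    p0 <- simulateAcghProfile(cm, NULL, purity = 0.7, noiseSD = 0)
    expect_true(all(p0$lratio == 0))
    expect_true(all(p0$cn == 2L))

    ev <- data.frame(name = "del", chrom = "chr7", start = 1, end = 5e6,
                     cn = 0L)
    p1 <- simulateAcghProfile(cm, ev, purity = 0.8, noiseSD = 0)
    expect_equal(unname(p1$lratio[1:5]), rep(log2(0.2), 5),
                 tolerance = 1e-12)
    expect_equal(log2(0.2), -2.321928, tolerance = 1e-6)

    ev$cn <- 10L
    p2 <- simulateAcghProfile(cm, ev, purity = 0.8, noiseSD = 0)
    expect_equal(unname(p2$lratio[1]), log2(4.2), tolerance = 1e-12)
    expect_equal(log2(4.2), 2.070, tolerance = 1e-3)

    ## later events override earlier ones on overlap
    ev2 <- rbind(data.frame(name = "gain", chrom = "chr7", start = 1,
                            end = 2e7, cn = 3L), ev)
    p3 <- simulateAcghProfile(cm, ev2, purity = 0.8, noiseSD = 0)
    expect_equal(unname(p3$cn[1:5]), rep(10L, 5))

    ev$end <- 9e9
    expect_error(simulateAcghProfile(cm, ev, 0.8), "outside chromosome")
})

test_that("survival generator: exponential law, censoring flags", {
    s0 <- simulateSurvival(rep("a", 50), c(a = 0.2), censoringRate = 0,
                           seed = 81)
    expect_true(all(s0$event == 1L))

    s1 <- simulateSurvival(rep("a", 10000), c(a = 0.25), seed = 82)
    expect_lt(abs(mean(s1$time) - 4) / 4, 0.05)   # mean within 5% of 1/h

    s2 <- simulateSurvival(rep(c("a", "b"), 50), c(a = 0.2, b = 0.2),
                           censoringRate = 0.3, seed = 83)
    expect_true(all(s2$event %in% c(0L, 1L)))
    expect_gt(sum(s2$event == 0L), 0)

    expect_error(simulateSurvival("a", c(a = -1)), "positive")
    expect_error(simulateSurvival("a", c(b = 1)), "no hazard")
})

test_that("expression generator: exact planted effects at zero noise", {
    cfg <- simulationConfig(expression = list(noiseSD = 0, baselineSD = 0,
                                              nProbes = 500L))
    samples <- sprintf("S%03d", 1:8)
    classes <- setNames(rep(c("classical", "mesenchymal"), each = 4),
                        samples)
    cells <- setNames(rep(c("RT.responder", "RT.nonresponder"), 4), samples)
    se <- simulateExpression(cfg, classes, cells, seed = 84)
    e <- SummarizedExperiment::assay(se, "exprs")

    ## constant off planted structure
    untouched <- is.na(SummarizedExperiment::rowData(se)$markerClass) &
        is.na(SummarizedExperiment::rowData(se)$plantedSet)
    expect_equal(unname(apply(e[untouched, ], 1, function(v)
        diff(range(v)))), rep(0, sum(untouched)))

    ## planted immune effect: mean(set, responders) - mean(set, NR) = 1
    immune <- SummarizedExperiment::rowData(se)$plantedSet %in% "immune"
    resp <- cells == "RT.responder"
    expect_equal(mean(e[immune, resp]) - mean(e[immune, !resp]), 1,
                 tolerance = 1e-12)

    ## class marker effect visible for the right samples only
    mk <- SummarizedExperiment::rowData(se)$markerClass %in% "classical"
    expect_equal(mean(e[mk, classes == "classical"]) -
                 mean(e[mk, classes == "mesenchymal"]),
                 cfg$expression$classEffect, tolerance = 1e-12)

    expect_error(simulateExpression(cfg, setNames("nope", "S001"),
                                    cells[1]), "unknown class")
})

test_that("planted noisy effects obey the CLT bound", {
    cfg <- simulationConfig(expression = list(nProbes = 500L))
    n <- 40
    samples <- sprintf("S%03d", 1:n)
    classes <- setNames(rep(c("neural", "proneural"), each = n / 2),
                        samples)
    cells <- setNames(rep(c("RT.responder", "RT.nonresponder"),
                          each = n / 2), samples)
    se <- simulateExpression(cfg, classes, cells, seed = 85)
    e <- SummarizedExperiment::assay(se, "exprs")
    immune <- SummarizedExperiment::rowData(se)$plantedSet %in% "immune"
    resp <- cells == "RT.responder"
    diff <- mean(e[immune, resp]) - mean(e[immune, !resp])
    sigma <- cfg$expression$noiseSD
    nEff <- sum(immune) * (n / 2)
    expect_lt(abs(diff - 1), 3 * sigma * sqrt(2 / nEff))
})

test_that("cohort simulation is deterministic and internally consistent", {
    cfg <- simulationConfig(nClones = 400L,
                            expression = list(nProbes = 300L))
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(lratio(a$acgh), lratio(b$acgh))
    expect_identical(SummarizedExperiment::assay(a$expression),
                     SummarizedExperiment::assay(b$expression))
    expect_identical(a$metadata, b$metadata)

    ## different seed changes the draws
    c2 <- simulateCohort(simulationConfig(nClones = 400L,
                                          expression = list(nProbes = 300L),
                                          seed = 99L))
    expect_false(identical(lratio(a$acgh), lratio(c2$acgh)))

    ## planted carrier counts are exact per cell
    meta <- a$metadata
    carriers <- a$truth$carriers
    ctR <- meta$treatment == "CT" & meta$response == "responder"
    ctN <- meta$treatment == "CT" & meta$response == "nonresponder"
    expect_equal(sum(carriers[ctR, "p16_homdel"]), 9L)
    expect_equal(sum(carriers[ctN, "p16_homdel"]), 0L)
    expect_equal(sum(carriers[ctR, "egfr_amp"]), 9L)
    expect_equal(sum(carriers[ctN, "egfr_amp"]), 6L)

    ## RT response labels re-derived from PFS agree with the planted labels
    rt <- meta$treatment == "RT"
    rederived <- ifelse(meta$pfs_months[rt] > 10, "responder",
                        ifelse(meta$pfs_months[rt] < 5, "nonresponder",
                               "unassigned"))
    expect_equal(rederived, meta$response[rt])

    ## outputs pass the io validators on a round trip
    d <- withr::local_tempdir()
    writeSampleMetadata(meta, file.path(d, "meta.tsv"))
    expect_silent(readSampleMetadata(file.path(d, "meta.tsv")))
    writeCloneMap(cloneMap(a$acgh), file.path(d, "cm.tsv"))
    expect_identical(length(readCloneMap(file.path(d, "cm.tsv"))), 400L)
    writeGMT(a$geneSets, file.path(d, "sets.gmt"))
    expect_equal(geneSets(readGMT(file.path(d, "sets.gmt"))),
                 geneSets(a$geneSets))
})

test_that("an empty cohort cell warns but does not abort", {
    cfg <- simulationConfig(nClones = 200L,
                            cells = c(RT.responder = 4L,
                                      RT.nonresponder = 4L,
                                      CT.responder = 3L,
                                      CT.nonresponder = 0L),
                            expression = list(nProbes = 300L))
    expect_warning(sim <- simulateCohort(cfg), "empty cohort cell")
    expect_equal(ncol(lratio(sim$acgh)), 11L)
})
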