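## Replicate averaging, mode/robust-SD, tumor-cell-rate estimation and
## five-state thresholding.

test_that("replicate averaging uses non-missing spots only", {
    cm <- tinyCloneMap(3, "chr1")
    spots <- data.frame(
        clone_id = c(rep("CL001", 4), rep("CL002", 2), rep("CL003", 4)),
        replicate_index = c(1:4, 1:2, 1:4),
        log2_ratio = c(1, 1, 1, 1, 0.9, 1.1, 1, NA, 3, NA))
    avg <- averageReplicates(spots, cm)
    expect_equal(unname(avg), c(1, 1, 2))
    spots$clone_id[1] <- "nope"
    expect_error(averageReplicates(spots, cm), "'nope'")
})

test_that("profile mode and robust SD: degenerate, mixture, equivariance", {
    expect_equal(profileModeSD(rep(0.3, 25)), list(mode = 0.3, sd = 0))

    ## 80/20 noiseless mixture: mode at the majority level, MAD-about-mode 0
    x <- c(rep(0, 80), rep(-1, 20))
    ms <- profileModeSD(x)
    expect_equal(ms$mode, 0)
    expect_equal(ms$sd, 0)

    ## shifting the profile shifts the mode, not the spread
    set.seed(41)
    y <- c(rnorm(200, 0, 0.02), rnorm(50, -0.7, 0.02))
    a <- profileModeSD(y)
    b <- profileModeSD(y + 1.3)
    expect_equal(b$mode, a$mode + 1.3, tolerance = 1e-12)
    expect_equal(b$sd, a$sd, tolerance = 1e-12)
    expect_lt(abs(a$mode), 0.01)
})

test_that("tumor-cell rate inverts single-copy displacements exactly", {
    ## loss cluster at log2(0.6): R = 2 (1 - 0.6) = 0.8
    segs <- data.frame(mean = c(0, log2(0.6)), nClones = c(300, 60))
    est <- estimateTumorCellRate(segs, mode = 0, sd = 0.02)
    expect_equal(est$rTC, 0.8, tolerance = 1e-12)
    expect_equal(est$source, "loss")

    ## gain fallback: single-copy gain at log2(1 + R/2)
    segs <- data.frame(mean = c(0, log2(1.35)), nClones = c(300, 60))
    est <- estimateTumorCellRate(segs, mode = 0, sd = 0.02)
    expect_equal(est$rTC, 0.7, tolerance = 1e-12)
    expect_equal(est$source, "gain")

    ## deep-loss fallback: homozygous-deletion level log2(1 - R)
    segs <- data.frame(mean = c(0, log2(1 - 0.65)), nClones = c(300, 4))
    est <- estimateTumorCellRate(segs, mode = 0, sd = 0.02)
    expect_equal(est$rTC, 0.65, tolerance = 1e-12)
    expect_equal(est$source, "homdel")

    ## flat profile: default with warning
    segs <- data.frame(mean = 0, nClones = 300)
    expect_warning(est <- estimateTumorCellRate(segs, 0, 0.02), "default")
    expect_equal(est$rTC, 0.7)
    expect_equal(est$source, "default")

    ## small spurious segments may not drive the estimate
    segs <- data.frame(mean = c(0, -0.15, 0.4), nClones = c(300, 5, 2))
    expect_warning(est <- estimateTumorCellRate(segs, 0, 0.02), "default")
    expect_equal(est$source, "default")
})

test_that("noiseless purity recovery is exact over the purity grid", {
    for (R in seq(0.5, 0.9, by = 0.1)) {
        prof <- noiselessProfile(R, cn = 1)     # het loss on chr2
        fit1 <- segmentSignal(prof$lratio[1:50])
        fit2 <- segmentSignal(prof$lratio[51:100])
        segs <- rbind(fit1$segments, fit2$segments)
        sm <- c(fit1$smoothed, fit2$smoothed)
        ms <- profileModeSD(sm)
        expect_equal(ms$mode, 0)
        est <- estimateTumorCellRate(segs, ms$mode, ms$sd)
        expect_lt(abs(est$rTC - R), 1e-9)
    }
})

test_that("thresholds reproduce the closed forms at R = 0.8", {
    thr <- aberrationThresholds(0.8, sd = 0.05)
    expect_equal(unname(thr["homdel"]), log2(0.2), tolerance = 1e-12)
    expect_equal(unname(thr["homdel"]), -2.321928, tolerance = 1e-6)
    expect_equal(unname(thr["amp"]), log2(2.2), tolerance = 1e-12)
    expect_equal(unname(thr["amp"]), 1.137504, tolerance = 1e-6)
    expect_equal(unname(thr[c("loss", "gain")]), c(-0.05, 0.05))
    ## the noise guard only relaxes thresholds when residual noise is seen
    thr2 <- aberrationThresholds(0.8, sd = 0.05, residSd = 0.15)
    expect_gt(thr2[["homdel"]], thr[["homdel"]])
    expect_lt(thr2[["amp"]], thr[["amp"]])
})

test_that("five states: diploid profiles, inclusive boundaries, priorities", {
    ## noiseless diploid: all neutral (sd = 0 warns about degenerate bands)
    expect_warning(
        st <- callStates(rep(0, 20), mode = 0, sd = 0, rTC = 0.8),
        "degenerate")
    expect_true(all(st == "neutral"))

    ## noiseless cn = 0 at purity 0.8 sits exactly on the threshold:
    ## called homdel by the inclusive rule
    v <- c(0, log2(0.2), -0.5, 0.5, log2(2.2), 1.9)
    st <- callStates(v, mode = 0, sd = 0.05, rTC = 0.8)
    expect_equal(st, c("neutral", "homdel", "loss", "gain", "amp", "amp"))

    ## NA propagates
    expect_true(is.na(callStates(c(NA, 0), 0, 0.05, 0.8)[1]))
})

test_that("noiseless amp calls flag tumor copy number above the 5-copy
           boundary, independent of purity", {
    for (R in seq(0.5, 0.9, by = 0.1)) {
        for (cn in c(0, 1, 2, 3, 4, 5, 6, 8, 10)) {
            prof <- noiselessProfile(R, cn = cn)
            sm <- numeric(100)
            for (part in list(1:50, 51:100))
                sm[part] <- segmentSignal(prof$lratio[part])$smoothed
            ms <- profileModeSD(sm)
            st <- suppressWarnings(
                callStates(sm, ms$mode, ms$sd, rTC = R))
            isAmp <- st[prof$eventClones] == "amp"
            ## cn = 5 sits exactly on the amplicon threshold and is called
            ## amplified by the inclusive rule
            expect_true(all(isAmp == (cn >= 5)),
                        info = sprintf("R=%g cn=%d", R, cn))
        }
    }
})

test_that("calls are invariant to a global profile shift", {
    set.seed(42)
    cm <- tinyCloneMap(60, c("chr1", "chr2"))
    lr <- matrix(rnorm(120, 0, 0.15), ncol = 1,
                 dimnames = list(names(cm), "s1"))
    lr[61:120, 1] <- lr[61:120, 1] + log2(1 - 0.8 / 2)   # het loss chr2
    run <- function(m) {
        ae <- AcghExperiment(m, cm)
        ae <- segmentProfiles(ae)
        ae <- estimateProfileStats(ae)
        ae <- suppressWarnings(callAberrations(ae))
        aberrationCalls(ae)[, 1]
    }
    expect_identical(run(lr), run(lr + 0.9))
})

test_that("noisy cohort calling meets its operating characteristics", {
    fx <- calledCohort()
    cn <- trueCopyNumber(fx$ae)
    calls <- aberrationCalls(fx$ae)
    st <- as.data.frame(profileStats(fx$ae))

    ## purity recovered well for samples with usable single-copy events
    usable <- st$rTCSource %in% c("loss", "gain")
    expect_gt(mean(usable), 0.9)
    expect_lt(median(abs(st$rTC[usable] - st$purity[usable])), 0.03)

    ## single-copy event clones: >= 95% called as their event
    sc <- cn == 1 | cn == 3
    acc <- mean(ifelse(cn[sc] == 1, calls[sc] == "loss",
                       calls[sc] == "gain"))
    expect_gte(acc, 0.95)

    ## homozygous deletions: >= 90% sensitivity; amplicons detected
    expect_gte(mean(calls[cn == 0] == "homdel"), 0.90)
    expect_gte(mean(calls[cn == 10] == "amp"), 0.95)
})
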