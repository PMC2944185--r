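## Clustering, centroid subtyping, moderated t, top-gene selection,
## fold-change filtering and gene-set over-representation.

makeExpr <- function(nProbes, samples, means = 0, sd = 1, seed = 71) {
    set.seed(seed)
    m <- matrix(rnorm(nProbes * length(samples), means, sd), nProbes,
                dimnames = list(sprintf("p%04d", seq_len(nProbes)), samples))
    m
}

test_that("Ward/1-Pearson clustering: duplicates, singletons, merge oracle", {
    e <- makeExpr(60, paste0("s", 1:6))
    e[, "s2"] <- e[, "s1"]                    # identical pair merges first
    cl <- wardPearsonCluster(e, k = 3)
    expect_equal(cl$tree$merge[1, ], c(-1, -2))
    expect_equal(cl$labels[["s1"]], cl$labels[["s2"]])

    expect_equal(unname(wardPearsonCluster(e, k = 6)$labels), 1:6)

    ## 4-sample merge sequence against the brute-force Lance-Williams oracle
    for (seed in 72:75) {
        e4 <- makeExpr(40, paste0("s", 1:4), seed = seed)
        D <- 1 - cor(e4)
        oracle <- bruteWard(D)
        tree <- wardPearsonCluster(e4, k = 2)$tree
        hts <- sort(vapply(oracle, `[[`, numeric(1), "height"))
        expect_equal(sort(tree$height), hts, tolerance = 1e-10)
        ## final two-cluster partition agrees
        oraclePair <- oracle[[2]]$members
        labs <- cutree(tree, 2)
        expect_true(length(unique(labs[oraclePair])) == 1 ||
                    length(oraclePair) != 2)
    }

    e[, "s3"] <- 5
    expect_error(wardPearsonCluster(e, 2), "zero-variance sample: 's3'")
})

test_that("centroid classifier reclassifies noiseless archetypes perfectly", {
    classes <- c("A", "B", "C")
    nP <- 60
    arch <- matrix(rnorm(nP * 3), nP, 3,
                   dimnames = list(sprintf("p%04d", 1:nP), classes))
    ## reference: two exact copies of each archetype plus tiny jitter-free
    ## duplicates (class needs >= 2 samples)
    ref <- arch[, rep(classes, each = 2)]
    colnames(ref) <- paste0("r", 1:6)
    labels <- setNames(rep(classes, each = 2), colnames(ref))
    model <- buildCentroidClassifier(ref, labels)
    expect_equal(modelClasses(model), classes)

    ## self-reclassification
    self <- classifyByCentroid(model, ref)
    expect_equal(self$class, unname(labels[self$sample]))
    expect_true(all(self$correlation > 0.99))

    ## a fresh noiseless cohort of archetypes classifies 100% correctly
    cohort <- arch[, c(1, 1, 2, 3, 2, 3, 1)]
    colnames(cohort) <- paste0("t", 1:7)
    got <- classifyByCentroid(model, cohort)
    expect_equal(got$class, classes[c(1, 1, 2, 3, 2, 3, 1)])

    ## the negative of a centroid must not classify as that class
    neg <- -arch[, "A", drop = FALSE]
    colnames(neg) <- "n1"
    gotNeg <- suppressWarnings(classifyByCentroid(model,
                                                  cbind(cohort, neg)))
    expect_false(gotNeg$class[gotNeg$sample == "n1"] == "A")

    ## probe order does not matter
    model2 <- buildCentroidClassifier(ref[sample(nP), ], labels)
    expect_equal(centroids(model2)[rownames(centroids(model)), ],
                 centroids(model))

    expect_error(buildCentroidClassifier(ref[, 1:5], labels[1:5]),
                 "fewer than 2")
})

test_that("moderated t: nulls, pooled-t collapse, limma agreement", {
    e <- makeExpr(200, paste0("s", 1:12), seed = 76)
    g <- setNames(rep(c("x", "y"), each = 6), colnames(e))
    ## a gene with exactly equal group means: t = 0, p = 1
    e[1, ] <- c(1, 2, 3, 1, 2, 3, 3, 2, 1, 3, 2, 1)
    de <- moderatedTTest(e, g)
    expect_equal(de$table$tMod[1], 0)
    expect_equal(de$table$p[1], 1)

    ## identical per-gene variances: d0 = Inf and t equals the pooled t
    e2 <- matrix(0, 50, 8, dimnames = list(sprintf("g%02d", 1:50),
                                           paste0("s", 1:8)))
    base <- c(-1.5, -0.5, 0.5, 1.5)
    for (i in 1:50) e2[i, ] <- c(base, base + i * 0.1)
    g2 <- setNames(rep(c("x", "y"), each = 4), colnames(e2))
    de2 <- moderatedTTest(e2, g2)
    expect_equal(de2$fit$d0, Inf)
    ordinary <- apply(e2, 1, function(v)
        t.test(v[1:4], v[5:8], var.equal = TRUE)$statistic)
    expect_equal(de2$table$tMod, unname(ordinary), tolerance = 1e-9)

    ## label swap negates t, keeps p
    gSwap <- setNames(rep(c("y", "x"), each = 6), colnames(e))
    deSwap <- moderatedTTest(e, gSwap)
    expect_equal(deSwap$table$tMod, -de$table$tMod)
    expect_equal(deSwap$table$p, de$table$p)

    ## gene order invariance
    o <- sample(nrow(e))
    deo <- moderatedTTest(e[o, ], g)
    expect_equal(deo$table$tMod[order(o)], de$table$tMod)

    ## agreement with the reference empirical-Bayes implementation
    skip_if_not_installed("limma")
    design <- stats::model.matrix(~ 0 + factor(g, levels = c("x", "y")))
    colnames(design) <- c("x", "y")
    fit <- limma::lmFit(e, design)
    fit <- limma::contrasts.fit(fit, limma::makeContrasts(x - y,
                                                          levels = design))
    fit <- limma::eBayes(fit)
    expect_equal(de$fit$d0, fit$df.prior, tolerance = 1e-6)
    expect_equal(de$fit$s02, fit$s2.prior, tolerance = 1e-6)
    expect_equal(de$table$tMod, unname(fit$t[, 1]), tolerance = 1e-6)
    expect_equal(de$table$p, unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("top-gene selection is a disjoint per-direction split", {
    e <- makeExpr(300, paste0("s", 1:10), seed = 77)
    g <- setNames(rep(c("x", "y"), each = 5), colnames(e))
    de <- moderatedTTest(e, g)
    top <- selectTopGenes(de, 50)
    expect_equal(length(top$upInA), 50L)
    expect_equal(length(top$upInB), 50L)
    expect_equal(length(intersect(top$upInA, top$upInB)), 0L)
    tab <- de$table
    expect_true(all(tab$delta[match(top$upInA, tab$probe)] > 0))
    expect_true(all(tab$delta[match(top$upInB, tab$probe)] < 0))

    ## short side returns what exists, with a warning
    e3 <- e[1:30, ]
    de3 <- moderatedTTest(e3, g)
    w <- capture_warnings(top3 <- selectTopGenes(de3, 25))
    expect_match(w, "requested 25", all = FALSE)
    expect_equal(length(top3$upInA) + length(top3$upInB), 30L)
})

test_that("p/fold-change filter keeps and drops by both criteria", {
    tab <- data.frame(probe = c("a", "b", "c", "d"),
                      delta = c(log2(1.6), log2(1.2), -log2(1.8), log2(2)),
                      fc = c(1.6, 1.2, 1 / 1.8, 2),
                      tMod = 0, p = c(0.04, 0.04, 0.01, 0.2),
                      q = 1,
                      direction = c("up_in_A", "up_in_A", "up_in_B",
                                    "up_in_A"))
    res <- filterDE(tab)
    expect_equal(res$upInA, "a")        # b fails FC, d fails p
    expect_equal(res$upInB, "c")        # FC < 1 counted via 1/fc
    expect_equal(unname(res$counts), c(1L, 1L))
})

test_that("filter recovers planted two-fold genes with high power", {
    set.seed(78)
    nP <- 600; nTrue <- 100
    samples <- paste0("s", 1:30)
    e <- makeExpr(nP, samples, sd = 0.5, seed = 78)
    g <- setNames(rep(c("x", "y"), each = 15), samples)
    e[1:nTrue, g == "x"] <- e[1:nTrue, g == "x"] + 1   # 2-fold in x
    de <- moderatedTTest(e, g)
    res <- filterDE(de)
    recovered <- intersect(res$upInA, sprintf("p%04d", 1:nTrue))
    expect_gte(length(recovered), 90)
})

test_that("hypergeometric enrichment matches closed forms and finds the
           planted set", {
    gsc <- GeneSetCollection(list(hit = paste0("g", 1:5),
                                  all = paste0("g", 1:10)),
                             universe = paste0("g", 1:10))
    res <- hypergeometricEnrichment(paste0("g", 1:5), gsc)
    expect_equal(res$p[res$set == "hit"], 1 / choose(10, 5),
                 tolerance = 1e-12)
    expect_equal(res$p[res$set == "all"], 1)   # set = universe

    ## zero overlap
    gsc2 <- GeneSetCollection(list(s = paste0("g", 1:3)),
                              universe = paste0("g", 1:10))
    expect_equal(hypergeometricEnrichment(paste0("g", 8:10), gsc2)$p, 1)

    expect_error(hypergeometricEnrichment("gX", gsc2), "outside")

    ## planted contrast: the immune set tops the responder-up enrichment
    fx <- calledCohort()
    expr <- SummarizedExperiment::assay(fx$sim$expression, "exprs")
    meta <- fx$sim$metadata
    rt <- meta$sample_id[meta$treatment == "RT"]
    g <- setNames(factor(meta$response,
                         levels = c("responder", "nonresponder")),
                  meta$sample_id)[rt]
    de <- moderatedTTest(expr[, rt], g)
    top <- selectTopGenes(de, 100)
    pg <- setNames(SummarizedExperiment::rowData(fx$sim$expression)$gene,
                   rownames(fx$sim$expression))
    up <- hypergeometricEnrichment(unname(pg[top$upInA]), fx$sim$geneSets)
    dn <- hypergeometricEnrichment(unname(pg[top$upInB]), fx$sim$geneSets)
    expect_equal(up$set[1], "immune")
    expect_equal(dn$set[1], "hypoxia")
})

test_that("probes collapse to genes by the highest-variance probe", {
    e <- makeExpr(4, paste0("s", 1:6), seed = 79)
    e[2, ] <- e[2, ] * 10
    pg <- c(p0001 = "G1", p0002 = "G1", p0003 = "G2", p0004 = "G2")
    rep <- collapseToGenes(e, pg)
    expect_equal(rep[["G1"]], "p0002")
    expect_equal(length(rep), 2L)
})
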