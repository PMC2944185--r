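## Transcriptomics: Ward/1-Pearson clustering, centroid subtyping,
## empirical-Bayes moderated t, top-gene selection, fold-change filtering,
## and hypergeometric gene-set over-representation.

.exprMatrix <- function(expr) {
    if (is(expr, "SummarizedExperiment")) expr <- assay(expr)
    expr <- as.matrix(expr)
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("expression matrix needs probe row names and sample col names")
    if (anyDuplicated(rownames(expr)))
        stop("duplicated probe identifier: '",
             rownames(expr)[duplicated(rownames(expr))][1L], "'")
    expr
}

#' Hierarchical clustering with Ward linkage on 1 - Pearson correlation
#'
#' Sample dissimilarity is `1 - Pearson(sample i, sample j)` over all
#' probes; agglomeration applies the Ward Lance-Williams update directly to
#' that dissimilarity (the classical `ward.D` convention of microarray
#' toolchains, not `ward.D2`), and the tree is cut into `k` clusters.
#'
#' @param expr probes x samples matrix (or SummarizedExperiment).
#' @param k number of clusters to cut.
#' @return A list with `labels` (named cluster index per sample) and `tree`
#'   (the `hclust` object).
#' @export
wardPearsonCluster <- function(expr, k) {
    expr <- .exprMatrix(expr)
    if (k < 1L || k > ncol(expr))
        stop("'k' must be between 1 and the number of samples")
    sds <- apply(expr, 2L, sd)
    if (any(sds == 0))
        stop("zero-variance sample: '",
             colnames(expr)[which(sds == 0)[1L]], "'")
    D <- 1 - cor(expr)
    tree <- hclust(as.dist(D), method = "ward.D")
    list(labels = cutree(tree, k = k), tree = tree)
}

#' Build a nearest-centroid classifier from reference expression
#'
#' Each probe is z-scored across the reference samples; the centroid of a
#' class is the per-class mean of the standardized values. The reference
#' standardization (per-probe mean and sd) is stored with the model.
#'
#' @param refExpr probes x samples reference expression matrix.
#' @param labels named class label per reference sample; every class needs
#'   at least 2 samples.
#' @param probes probe subset to build the model on (default all).
#' @return A [CentroidModel-class].
#' @export
buildCentroidClassifier <- function(refExpr, labels,
                                    probes = rownames(refExpr)) {
    refExpr <- .exprMatrix(refExpr)
    miss <- setdiff(probes, rownames(refExpr))
    if (length(miss) > 0L)
        stop("probe(s) absent from the reference: ",
             paste(head(miss, 3L), collapse = ", "))
    refExpr <- refExpr[probes, , drop = FALSE]
    if (is.null(names(labels))) {
        if (length(labels) != ncol(refExpr))
            stop("'labels' must be named by sample or match column count")
        names(labels) <- colnames(refExpr)
    }
    labels <- labels[colnames(refExpr)]
    tab <- table(labels)
    if (length(tab) < 2L) stop("need at least 2 classes")
    if (any(tab < 2L))
        stop("class with fewer than 2 reference samples: '",
             names(tab)[tab < 2L][1L], "'")
    mu <- rowMeans(refExpr)
    sdv <- apply(refExpr, 1L, sd)
    if (any(sdv == 0))
        stop("zero-variance probe in the reference: '",
             probes[which(sdv == 0)[1L]], "'")
    z <- (refExpr - mu) / sdv
    classes <- names(tab)
    cent <- vapply(classes, function(cl)
        rowMeans(z[, labels == cl, drop = FALSE]), numeric(nrow(z)))
    dimnames(cent) <- list(probes, classes)
    names(mu) <- names(sdv) <- probes
    new("CentroidModel", centroids = cent, refMean = mu, refSd = sdv)
}

#' Classify samples by maximal centroid correlation
#'
#' Expression of the cohort being classified is z-scored per probe across
#' that cohort, and every sample is assigned the class whose centroid has
#' the largest Pearson correlation with the sample's standardized profile.
#' Probes missing from the cohort are dropped pairwise; fewer than 50%
#' shared probes is an error. Correlation ties go to the first class in
#' model order, with a warning.
#'
#' @param model a [CentroidModel-class].
#' @param expr probes x samples matrix (or SummarizedExperiment) to
#'   classify.
#' @return A data.frame with `sample`, `class`, `correlation`.
#' @export
classifyByCentroid <- function(model, expr) {
    expr <- .exprMatrix(expr)
    probes <- intersect(modelProbes(model), rownames(expr))
    if (length(probes) < 0.5 * length(modelProbes(model)))
        stop("fewer than 50% of model probes present in the expression data")
    e <- expr[probes, , drop = FALSE]
    mu <- rowMeans(e)
    sdv <- apply(e, 1L, sd)
    if (any(sdv == 0)) {
        warning(sum(sdv == 0), " zero-variance probe(s) set to z = 0",
                call. = FALSE)
        sdv[sdv == 0] <- Inf
    }
    z <- (e - mu) / sdv
    cent <- centroids(model)[probes, , drop = FALSE]
    cors <- cor(z, cent)
    tied <- apply(cors, 1L, function(r) sum(r == max(r)) > 1L)
    if (any(tied))
        warning("correlation tie for sample(s): ",
                paste(rownames(cors)[tied], collapse = ", "),
                "; first class in model order used", call. = FALSE)
    best <- apply(cors, 1L, which.max)
    data.frame(sample = colnames(expr),
               class = colnames(cent)[best],
               correlation = cors[cbind(seq_len(nrow(cors)), best)],
               stringsAsFactors = FALSE)
}

#' Empirical-Bayes moderated t-test between two groups
#'
#' Per-gene pooled two-sample variances `s_g^2` (df `d_g = n1 + n2 - 2`) are
#' shrunk toward a prior by moment matching on `log s_g^2`: with
#' `e_g = log s_g^2 - digamma(d_g/2) + log(d_g/2)`, the prior df solves
#' `trigamma(d0/2) = var(e) - trigamma(d_g/2)` (digamma/trigamma inversion)
#' and `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`. The moderated
#' variance is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the moderated t is
#' referred to a t distribution with `d_g + d0` df; q-values are
#' Benjamini-Hochberg across probes. When the log-variances show no excess
#' spread, `d0 = Inf` and `s0^2 = mean(s_g^2)`, so the moderated t collapses
#' to the ordinary pooled-variance t.
#'
#' @param expr probes x samples matrix (or SummarizedExperiment).
#' @param groups named two-level factor/character over the samples. The
#'   FIRST level (alphabetical for character input, or the factor's level
#'   order) is "group A": `delta = mean(A) - mean(B)` and
#'   `fc = 2^delta`.
#' @return A list with `table` (data.frame: `probe`, `delta`, `fc`, `tMod`,
#'   `p`, `q`, `direction` in `up_in_A`/`up_in_B`, sorted as input) and
#'   `fit` (`d0`, `s02`, `dg`, per-gene `s2`).
#' @export
moderatedTTest <- function(expr, groups) {
    expr <- .exprMatrix(expr)
    if (nrow(expr) < 2L) stop("need at least 2 probes")
    if (is.null(names(groups))) {
        if (length(groups) != ncol(expr))
            stop("'groups' must be named by sample or match column count")
        names(groups) <- colnames(expr)
    }
    ## preserve a caller-supplied level order (defines group A); character
    ## input falls back to alphabetical
    g <- droplevels(if (is.factor(groups)) groups[colnames(expr)]
                    else factor(as.character(groups[colnames(expr)])))
    if (nlevels(g) != 2L) stop("exactly two groups are required")
    n1 <- sum(g == levels(g)[1L]); n2 <- sum(g == levels(g)[2L])
    if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
    a <- expr[, g == levels(g)[1L], drop = FALSE]
    b <- expr[, g == levels(g)[2L], drop = FALSE]
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    delta <- m1 - m2
    s2 <- (rowSums((a - m1)^2) + rowSums((b - m2)^2)) / (n1 + n2 - 2)
    dg <- n1 + n2 - 2
    if (all(s2 == 0)) stop("all probes have zero pooled variance")
    if (any(s2 == 0)) {
        warning(sum(s2 == 0), " zero-variance probe(s) floored to the ",
                "smallest positive pooled variance", call. = FALSE)
        s2[s2 == 0] <- min(s2[s2 > 0])
    }
    e <- log(s2) - digamma(dg / 2) + log(dg / 2)
    evar <- var(e) - trigamma(dg / 2)
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
        sTilde2 <- (d0 * s02 + dg * s2) / (d0 + dg)
    } else {
        d0 <- Inf
        s02 <- mean(s2)
        sTilde2 <- rep(s02, length(s2))
    }
    tMod <- delta / sqrt(sTilde2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tMod), df = dg + d0)
    tab <- data.frame(probe = rownames(expr), delta = delta, fc = 2^delta,
                      tMod = tMod, p = p, q = bhAdjust(p),
                      direction = ifelse(delta > 0, "up_in_A",
                                         ifelse(delta < 0, "up_in_B", NA)),
                      stringsAsFactors = FALSE, row.names = NULL)
    list(table = tab,
         fit = list(d0 = d0, s02 = s02, dg = dg, s2 = s2,
                    groupA = levels(g)[1L], groupB = levels(g)[2L]))
}

#' Select the top differentially expressed genes per direction
#'
#' Per direction (up in A / up in B), the `nPerSide` probes with the
#' smallest p-values; ties broken lexicographically by probe id. If a
#' direction has fewer probes than requested, all available are returned
#' with a warning. Probes with `delta == 0` belong to neither direction.
#'
#' @param de result of [moderatedTTest()] (or its `table`).
#' @param nPerSide probes to take per direction (default 500).
#' @return A list with character vectors `upInA` and `upInB` (disjoint).
#' @export
selectTopGenes <- function(de, nPerSide = 500L) {
    tab <- if (is.list(de) && !is.data.frame(de)) de$table else de
    pick <- function(dir) {
        sub <- tab[!is.na(tab$direction) & tab$direction == dir, ,
                   drop = FALSE]
        sub <- sub[order(sub$p, sub$probe), , drop = FALSE]
        if (nrow(sub) < nPerSide)
            warning("only ", nrow(sub), " probes ", dir,
                    " (requested ", nPerSide, ")", call. = FALSE)
        head(sub$probe, nPerSide)
    }
    list(upInA = pick("up_in_A"), upInB = pick("up_in_B"))
}

#' Filter differential expression by raw p and fold change
#'
#' A probe is kept iff `p < pMax` and `max(fc, 1/fc) > fcMin` (raw p, no
#' adjustment: the filter reproduces the study-style "p < 0.05 and fold
#' change > 1.5" gene counts).
#'
#' @param de result of [moderatedTTest()] (or its `table`).
#' @param pMax raw p-value cutoff (default 0.05).
#' @param fcMin linear fold-change cutoff (default 1.5).
#' @return A list with `upInA`, `upInB` (kept probe ids) and `counts`
#'   (named vector of the two list lengths).
#' @export
filterDE <- function(de, pMax = 0.05, fcMin = 1.5) {
    tab <- if (is.list(de) && !is.data.frame(de)) de$table else de
    keep <- tab$p < pMax & pmax(tab$fc, 1 / tab$fc) > fcMin
    upA <- tab$probe[keep & !is.na(tab$direction) &
                     tab$direction == "up_in_A"]
    upB <- tab$probe[keep & !is.na(tab$direction) &
                     tab$direction == "up_in_B"]
    list(upInA = upA, upInB = upB,
         counts = c(upInA = length(upA), upInB = length(upB)))
}

#' Collapse probes to genes by highest variance
#'
#' For enrichment, each gene is represented by its highest-variance probe.
#'
#' @param expr probes x samples matrix.
#' @param probeGene named character vector mapping probe id to gene symbol.
#' @return Named character vector mapping each gene to its representative
#'   probe.
#' @export
collapseToGenes <- function(expr, probeGene) {
    expr <- .exprMatrix(expr)
    probes <- intersect(rownames(expr), names(probeGene))
    v <- apply(expr[probes, , drop = FALSE], 1L, var)
    o <- order(probeGene[probes], -v, probes)
    probes <- probes[o]
    genes <- probeGene[probes]
    keep <- !duplicated(genes)
    setNames(probes[keep], genes[keep])
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, `p = P(X >= k)` with
#' `X ~ Hypergeometric(N = |universe|, K = |set|, n = |list|)`;
#' Benjamini-Hochberg q-values across sets.
#'
#' @param geneList character vector of genes (must lie in the universe).
#' @param gsc a [GeneSetCollection-class].
#' @param universe optional override of the collection's universe.
#' @return A data.frame sorted by p: `set`, `overlap` (k), `setSize` (K),
#'   `listSize` (n), `universeSize` (N), `p`, `q`.
#' @export
hypergeometricEnrichment <- function(geneList, gsc, universe = NULL) {
    if (is.null(universe)) universe <- geneUniverse(gsc)
    universe <- unique(universe)
    if (length(universe) == 0L) stop("empty universe")
    out <- setdiff(geneList, universe)
    if (length(out) > 0L)
        stop("gene(s) outside the universe: ",
             paste(head(out, 3L), collapse = ", "))
    geneList <- unique(geneList)
    N <- length(universe); n <- length(geneList)
    sets <- lapply(geneSets(gsc), intersect, y = universe)
    res <- do.call(rbind, lapply(names(sets), function(nm) {
        K <- length(sets[[nm]])
        k <- length(intersect(geneList, sets[[nm]]))
        data.frame(set = nm, overlap = k, setSize = K, listSize = n,
                   universeSize = N,
                   p = hypergeometricTail(N, K, n, k),
                   stringsAsFactors = FALSE)
    }))
    res$q <- bhAdjust(res$p)
    res[order(res$p, res$set), , drop = FALSE]
}
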