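## Synthetic cohort generator: aCGH profiles, expression, metadata and
## survival with the statistical structure the downstream analysis assumes.
## The copy-number model is the same two-population mixture the caller
## inverts: expected log2 ratio = log2((R * cn + 2 (1 - R)) / 2).

## Deterministic child seeds below 2^31, fanned out from the global seed so
## each generator stage is individually reproducible.
.childSeed <- function(seed, k)
    as.integer((as.numeric(seed) * 48271 + k * 2654435) %% 2147483629)

.CELLS <- c("RT.responder", "RT.nonresponder", "CT.responder",
            "CT.nonresponder")

#' Rounded human-like chromosome lengths
#'
#' Autosomes plus X, rounded to the Mb; the exact genome build is irrelevant
#' at the desk scale of the simulation.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
defaultChromosomes <- function() {
    mb <- c(chr1 = 249, chr2 = 243, chr3 = 198, chr4 = 191, chr5 = 181,
            chr6 = 171, chr7 = 159, chr8 = 146, chr9 = 141, chr10 = 136,
            chr11 = 135, chr12 = 134, chr13 = 115, chr14 = 107,
            chr15 = 103, chr16 = 90, chr17 = 81, chr18 = 78, chr19 = 59,
            chr20 = 63, chr21 = 48, chr22 = 51, chrX = 155)
    mb * 1e6
}

#' Default planted copy-number event table
#'
#' Glioblastoma-typical events: whole chromosome 7 gain, whole chromosome 10
#' loss, a focal 9p21 homozygous deletion (p16/CDKN2A locus) and a 7p11 EGFR
#' amplicon. Per-cell probabilities encode the planted response contrasts:
#' 9p21 homozygous deletion in 9/11 chemotherapy responders vs 0/17
#' non-responders, EGFR amplicons in 9/11 vs 6/17.
#'
#' @return data.frame with columns `name`, `chrom`, `start`, `end`, `cn`
#'   and one probability column per treatment x response cell. Events are
#'   applied in row order; later rows override earlier ones on overlap.
#' @export
defaultEventTable <- function() {
    data.frame(
        name = c("chr7_gain", "chr10_loss", "p16_homdel", "egfr_amp"),
        chrom = c("chr7", "chr10", "chr9", "chr7"),
        start = c(1, 1, 21500001, 54500001),
        end = c(159e6, 136e6, 24300000, 56000000),
        cn = c(3L, 1L, 0L, 10L),
        RT.responder = c(0.8, 0.8, 0.40, 0.45),
        RT.nonresponder = c(0.8, 0.8, 0.40, 0.45),
        CT.responder = c(0.8, 0.8, 9 / 11, 9 / 11),
        CT.nonresponder = c(0.8, 0.8, 0, 6 / 17),
        stringsAsFactors = FALSE)
}

#' Full parameterization of the synthetic cohort
#'
#' Defaults emulate the structure of the study the pipeline targets: 4,434
#' BAC clones tiling a human-like genome at ~670 kb, a two-arm cohort with
#' 21/18 radiotherapy responders/non-responders and 11/17 first-line
#' chemotherapy responders/non-responders, planted GBM copy-number events
#' (see [defaultEventTable()]), four expression subtypes with planted
#' immune/hypoxia/stem-cell gene-set effects, and exponential survival with
#' the progression-free-survival response rule (responders > 10 months,
#' non-responders < 5).
#'
#' @param nClones number of clones (default 4434).
#' @param cloneSpacing nominal inter-clone spacing in bp (default 670000);
#'   clones are spread evenly so that `nClones` fit the genome, giving an
#'   effective spacing close to this value.
#' @param cloneWidth clone length in bp.
#' @param chromosomes named vector of chromosome lengths.
#' @param cells named sample counts per treatment x response cell.
#' @param events planted event table, see [defaultEventTable()]. Per-cell
#'   frequencies are planted as exact counts (`round(p * n)` carriers drawn
#'   at random), so the planted contrasts are reproduced exactly.
#' @param purityRange tumor-cell rate range; purity is uniform per sample.
#' @param noiseSD per-clone log2 noise (default 0.15).
#' @param expression list of expression parameters: `nProbes`, `classes`,
#'   `nMarkersPerClass`, `classEffect` (log2), `baselineMean`, `baselineSD`,
#'   `noiseSD`, `setSize`, `nRandomSets`, `setEffects` (data.frame
#'   set/cell/effect), `classProbs` (cells x classes subtype mixture).
#' @param survival list: `pfsHazard` per cell (1/months), `osExtraHazard`,
#'   `censoringRate`, `pfsThresholds` (short/long PFS cutoffs, months).
#' @param mgmtMethylated per-cell MGMT promoter methylation rates.
#' @param seed global seed; fixes all randomness.
#' @return Validated configuration list (class `SimulationConfig`).
#' @export
simulationConfig <- function(nClones = 4434L,
                             cloneSpacing = 670000,
                             cloneWidth = 150000,
                             chromosomes = defaultChromosomes(),
                             cells = c(RT.responder = 21L,
                                       RT.nonresponder = 18L,
                                       CT.responder = 11L,
                                       CT.nonresponder = 17L),
                             events = defaultEventTable(),
                             purityRange = c(0.5, 0.9),
                             noiseSD = 0.15,
                             expression = list(),
                             survival = list(),
                             mgmtMethylated = c(RT.responder = 0.4,
                                                RT.nonresponder = 0.4,
                                                CT.responder = 3 / 11,
                                                CT.nonresponder = 14 / 17),
                             seed = 17L) {
    exprDefaults <- list(
        nProbes = 2000L,
        classes = c("classical", "mesenchymal", "neural", "proneural"),
        nMarkersPerClass = 20L,
        classEffect = 1.5,
        baselineMean = 7, baselineSD = 1,
        noiseSD = 0.5,
        setSize = 50L,
        nRandomSets = 10L,
        setEffects = data.frame(
            set = c("immune", "hypoxia", "stemcell"),
            cell = c("RT.responder", "RT.nonresponder", "CT.nonresponder"),
            effect = c(1, 1, 1),
            stringsAsFactors = FALSE),
        classProbs = rbind(
            RT.responder = c(0.15, 0.40, 0.25, 0.20),
            RT.nonresponder = c(0.50, 0.12, 0.08, 0.30),
            CT.responder = c(0.60, 0.08, 0.24, 0.08),
            CT.nonresponder = c(0.06, 0.52, 0.06, 0.36)))
    expression <- utils::modifyList(exprDefaults, expression)
    colnames(expression$classProbs) <- expression$classes
    survDefaults <- list(
        pfsHazard = c(RT.responder = 0.08, RT.nonresponder = 0.35,
                      CT.responder = 0.07, CT.nonresponder = 0.30),
        osExtraHazard = 0.08,
        censoringRate = 0.15,
        pfsThresholds = c(short = 5, long = 10))
    survival <- utils::modifyList(survDefaults, survival)
    cfg <- list(nClones = as.integer(nClones), cloneSpacing = cloneSpacing,
                cloneWidth = cloneWidth, chromosomes = chromosomes,
                cells = cells, events = events, purityRange = purityRange,
                noiseSD = noiseSD, expression = expression,
                survival = survival, mgmtMethylated = mgmtMethylated,
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' Validate a simulation configuration
#'
#' @param config a `SimulationConfig`.
#' @return The config, invisibly; errors describe the first violated
#'   invariant.
#' @export
validateSimulationConfig <- function(config) {
    stopifnot(config$nClones >= 1L, config$cloneSpacing > 0,
              config$cloneWidth > 0)
    if (is.null(names(config$chromosomes)))
        stop("chromosome lengths must be named")
    if (!all(.CELLS %in% names(config$cells)))
        stop("cells must name all of: ", paste(.CELLS, collapse = ", "))
    ev <- config$events
    probCols <- intersect(.CELLS, colnames(ev))
    pr <- as.matrix(ev[, probCols])
    if (any(pr < 0 | pr > 1)) stop("event probabilities must lie in [0, 1]")
    if (any(ev$cn < 0 | ev$cn != round(ev$cn)))
        stop("event copy numbers must be nonnegative integers")
    if (!(config$purityRange[1L] > 0 && config$purityRange[2L] < 1 &&
          config$purityRange[1L] <= config$purityRange[2L]))
        stop("purityRange must lie inside (0, 1)")
    if (config$noiseSD < 0) stop("noiseSD must be nonnegative")
    if (any(config$survival$pfsHazard <= 0))
        stop("survival hazards must be positive")
    if (config$survival$censoringRate < 0 ||
        config$survival$censoringRate > 1)
        stop("censoringRate must lie in [0, 1]")
    invisible(config)
}

#' Build the clone map of a configuration
#'
#' Clones are allocated to chromosomes proportionally to length (largest
#' remainder) and placed at even spacing.
#'
#' @param config a [simulationConfig()].
#' @return A [CloneMap-class] with seqlengths set.
#' @export
buildCloneMap <- function(config = simulationConfig()) {
    chr <- config$chromosomes
    share <- chr / sum(chr) * config$nClones
    n <- floor(share)
    rem <- config$nClones - sum(n)
    if (rem > 0) {
        o <- order(share - n, decreasing = TRUE)
        n[o[seq_len(rem)]] <- n[o[seq_len(rem)]] + 1L
    }
    w <- config$cloneWidth
    pieces <- lapply(names(chr), function(ch) {
        m <- n[[ch]]
        if (m == 0L) return(NULL)
        centers <- (seq_len(m) - 0.5) * chr[[ch]] / m
        start <- pmax(1, round(centers - w / 2))
        data.frame(chrom = ch, start = start, end = pmin(start + w - 1,
                                                         chr[[ch]]))
    })
    df <- do.call(rbind, pieces)
    ids <- sprintf("BAC%05d", seq_len(nrow(df)))
    CloneMap(ids, df$chrom, df$start, df$end, zeroBased = FALSE,
             seqlengths = chr)
}

#' Simulate one array-CGH profile
#'
#' Per-clone ratio `log2((purity * cn + (1 - purity) * 2) / 2) +
#' Normal(0, noiseSD)`, with `cn = 2` outside the given events. Events are
#' applied in row order; later events override earlier ones on overlapping
#' clones.
#'
#' @param cloneMap a [CloneMap-class] (with seqlengths for bounds checking).
#' @param events data.frame of this sample's events: `chrom`, `start`,
#'   `end`, `cn` (1-based closed bp).
#' @param purity tumor-cell rate in (0, 1).
#' @param noiseSD log2 noise standard deviation.
#' @param seed optional seed.
#' @return A list with `lratio` and `cn`, both aligned to `cloneMap`.
#' @export
simulateAcghProfile <- function(cloneMap, events, purity, noiseSD = 0.15,
                                seed = NULL) {
    stopifnot(purity > 0, purity < 1, noiseSD >= 0)
    if (!is.null(seed)) set.seed(seed)
    cn <- rep(2L, length(cloneMap))
    chrom <- as.character(seqnames(cloneMap))
    sl <- GenomeInfoDb::seqlengths(cloneMap)
    if (!is.null(events) && nrow(events) > 0L) {
        for (i in seq_len(nrow(events))) {
            ch <- events$chrom[i]
            if (!ch %in% chrom)
                stop("event chromosome '", ch, "' not in the clone map")
            len <- sl[[ch]]
            if (!is.na(len) && (events$start[i] < 1 || events$end[i] > len))
                stop("event '",
                     if ("name" %in% colnames(events)) events$name[i] else i,
                     "' outside chromosome bounds")
            idx <- which(chrom == ch & start(cloneMap) <= events$end[i] &
                         end(cloneMap) >= events$start[i])
            cn[idx] <- as.integer(events$cn[i])
        }
    }
    mu <- log2((purity * cn + (1 - purity) * 2) / 2)
    lr <- mu + if (noiseSD > 0) rnorm(length(cn), 0, noiseSD) else 0
    list(lratio = setNames(lr, names(cloneMap)),
         cn = setNames(cn, names(cloneMap)))
}

#' Simulate exponential survival with independent censoring
#'
#' Times are exponential with the group's hazard; a censored subject's
#' observed time is uniform on (0, T).
#'
#' @param groupLabels vector of group labels, one per subject.
#' @param hazards named positive hazards (1/months) per group.
#' @param censoringRate probability a subject is censored.
#' @param seed optional seed.
#' @return data.frame with `time`, `event`, `group`.
#' @export
simulateSurvival <- function(groupLabels, hazards, censoringRate = 0,
                             seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    groupLabels <- as.character(groupLabels)
    miss <- setdiff(unique(groupLabels), names(hazards))
    if (length(miss) > 0L)
        stop("no hazard for group(s): ", paste(miss, collapse = ", "))
    if (any(hazards <= 0)) stop("hazards must be positive")
    if (censoringRate < 0 || censoringRate > 1)
        stop("censoringRate must lie in [0, 1]")
    n <- length(groupLabels)
    t <- rexp(n, rate = hazards[groupLabels])
    cens <- rbinom(n, 1L, censoringRate) == 1L
    time <- ifelse(cens, runif(n) * t, t)
    data.frame(time = time, event = as.integer(!cens),
               group = groupLabels, stringsAsFactors = FALSE)
}

#' Simulate an expression matrix with subtype and gene-set structure
#'
#' `expression = baseline + class-centroid effect + gene-set group effect +
#' Normal(0, noiseSD)`. The first `nMarkersPerClass * #classes` probes are
#' class markers; subsequent disjoint blocks of `setSize` probes carry the
#' planted gene-set effects, so every probe belongs to at most one planted
#' set. A one-to-one probe-to-gene map is emitted in `rowData`.
#'
#' @param config a [simulationConfig()] (its `$expression` entry is used).
#' @param classLabels named subtype per sample.
#' @param cellLabels named treatment x response cell per sample (drives the
#'   planted gene-set effects).
#' @param seed optional seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] (assay `exprs`,
#'   rowData `gene`, `markerClass`, `plantedSet`) with the
#'   [GeneSetCollection-class] in `metadata(x)$geneSets`.
#' @export
simulateExpression <- function(config, classLabels, cellLabels,
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    ex <- config$expression
    samples <- names(classLabels)
    if (is.null(samples)) stop("'classLabels' must be named by sample")
    unknown <- setdiff(unique(classLabels), ex$classes)
    if (length(unknown) > 0L)
        stop("unknown class label: '", unknown[1L], "'")
    cellLabels <- cellLabels[samples]
    nP <- ex$nProbes
    probes <- sprintf("PRB%05d", seq_len(nP))
    genes <- sprintf("GENE%05d", seq_len(nP))
    ## probe annotation: class marker blocks, then planted set blocks
    markerClass <- rep(NA_character_, nP)
    nm <- ex$nMarkersPerClass
    for (i in seq_along(ex$classes))
        markerClass[((i - 1) * nm + 1):(i * nm)] <- ex$classes[i]
    plantedSet <- rep(NA_character_, nP)
    offset <- length(ex$classes) * nm
    setNamesAll <- unique(ex$setEffects$set)
    for (i in seq_along(setNamesAll)) {
        idx <- (offset + (i - 1) * ex$setSize + 1):(offset + i * ex$setSize)
        if (max(idx) > nP) stop("nProbes too small for the planted sets")
        plantedSet[idx] <- setNamesAll[i]
    }
    ## expression = baseline + effects + noise
    baseline <- rnorm(nP, ex$baselineMean, ex$baselineSD)
    expr <- matrix(baseline, nP, length(samples),
                   dimnames = list(probes, samples))
    for (s in seq_along(samples)) {
        eff <- numeric(nP)
        eff[!is.na(markerClass) &
            markerClass == classLabels[[s]]] <- ex$classEffect
        hits <- ex$setEffects[ex$setEffects$cell == cellLabels[[s]], ,
                              drop = FALSE]
        for (j in seq_len(nrow(hits)))
            eff[!is.na(plantedSet) & plantedSet == hits$set[j]] <-
                eff[!is.na(plantedSet) & plantedSet == hits$set[j]] +
                hits$effect[j]
        expr[, s] <- expr[, s] + eff
    }
    if (ex$noiseSD > 0)
        expr <- expr + matrix(rnorm(length(expr), 0, ex$noiseSD), nrow(expr))
    ## gene sets: planted blocks plus random background sets
    sets <- lapply(setNamesAll, function(sn) genes[which(plantedSet == sn)])
    names(sets) <- setNamesAll
    pool <- genes[is.na(plantedSet) & is.na(markerClass)]
    for (i in seq_len(ex$nRandomSets))
        sets[[sprintf("random%02d", i)]] <- sample(pool, ex$setSize)
    gsc <- GeneSetCollection(sets, universe = genes)
    se <- SummarizedExperiment(
        assays = list(exprs = expr),
        rowData = DataFrame(gene = genes, markerClass = markerClass,
                            plantedSet = plantedSet, row.names = probes),
        colData = DataFrame(class = as.character(classLabels),
                            cell = as.character(cellLabels),
                            row.names = samples))
    metadata(se)$geneSets <- gsc
    se
}

## largest-remainder integer allocation of n among probabilities p
.allocateCounts <- function(n, p) {
    share <- p / sum(p) * n
    k <- floor(share)
    rem <- n - sum(k)
    if (rem > 0) {
        o <- order(share - k, decreasing = TRUE)
        k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
    }
    as.integer(k)
}

#' Simulate the full two-arm cohort
#'
#' Generates the clone map, per-sample aCGH profiles (planted events at
#' exact per-cell counts, uniform purity, Gaussian noise), subtype-structured
#' expression with planted gene-set effects, survival times consistent with
#' the progression-free-survival response rule (radiotherapy responders
#' above 10 months, non-responders below 5), and sample metadata. Deterministic
#' under the config seed. Radiotherapy response labels re-derived from the
#' simulated PFS agree with the planted labels by construction (verified
#' internally).
#'
#' @param config a [simulationConfig()].
#' @return A list: `acgh` ([AcghExperiment-class] with truth assays),
#'   `expression` (SummarizedExperiment), `metadata` (data.frame),
#'   `geneSets` ([GeneSetCollection-class]), `truth` (carrier matrix, class
#'   labels, purity, config).
#' @export
simulateCohort <- function(config = simulationConfig()) {
    validateSimulationConfig(config)
    seed <- config$seed
    if (any(config$cells == 0L))
        warning("empty cohort cell(s): ",
                paste(names(config$cells)[config$cells == 0L],
                      collapse = ", "), call. = FALSE)
    cm <- buildCloneMap(config)
    cells <- rep(names(config$cells), config$cells)
    n <- length(cells)
    samples <- sprintf("S%03d", seq_len(n))
    treatment <- sub("\\..*$", "", cells)
    response <- sub("^.*\\.", "", cells)

    ## planted event carriers: exact counts per cell
    set.seed(.childSeed(seed, 1L))
    ev <- config$events
    carriers <- matrix(FALSE, n, nrow(ev),
                       dimnames = list(samples, ev$name))
    for (i in seq_len(nrow(ev))) {
        for (cell in names(config$cells)) {
            idx <- which(cells == cell)
            nc <- round(ev[[cell]][i] * length(idx))
            if (nc > 0)
                carriers[sample(idx, nc), i] <- TRUE
        }
    }
    purity <- runif(n, config$purityRange[1L], config$purityRange[2L])

    ## aCGH profiles
    set.seed(.childSeed(seed, 2L))
    lr <- matrix(NA_real_, length(cm), n,
                 dimnames = list(names(cm), samples))
    cnm <- matrix(NA_integer_, length(cm), n,
                  dimnames = list(names(cm), samples))
    for (s in seq_len(n)) {
        prof <- simulateAcghProfile(cm, ev[carriers[s, ], , drop = FALSE],
                                    purity[s], config$noiseSD)
        lr[, s] <- prof$lratio
        cnm[, s] <- prof$cn
    }

    ## survival: PFS consistent with the planted RT response rule
    set.seed(.childSeed(seed, 3L))
    sv <- config$survival
    h <- sv$pfsHazard[cells]
    cutShort <- sv$pfsThresholds[["short"]]
    cutLong <- sv$pfsThresholds[["long"]]
    pfs <- numeric(n)
    for (s in seq_len(n)) {
        pfs[s] <- if (treatment[s] == "RT" && response[s] == "responder") {
            cutLong + rexp(1L, h[s])          # memoryless truncation > 10
        } else if (treatment[s] == "RT") {
            -log(1 - runif(1L) * (1 - exp(-h[s] * cutShort))) / h[s]
        } else {
            rexp(1L, h[s])
        }
    }
    os <- pfs + rexp(n, sv$osExtraHazard)
    cens <- rbinom(n, 1L, sv$censoringRate) == 1L
    osObs <- ifelse(cens, pfs + runif(n) * (os - pfs), os)
    rt <- treatment == "RT"
    rederived <- ifelse(pfs[rt] > cutLong, "responder",
                        ifelse(pfs[rt] < cutShort, "nonresponder",
                               "unassigned"))
    stopifnot(identical(rederived, response[rt]))

    ## MGMT methylation, exact counts per cell
    set.seed(.childSeed(seed, 4L))
    mgmt <- rep("unmethylated", n)
    for (cell in names(config$cells)) {
        idx <- which(cells == cell)
        nc <- round(config$mgmtMethylated[[cell]] * length(idx))
        if (nc > 0) mgmt[sample(idx, nc)] <- "methylated"
    }

    ## subtype labels: exact per-cell allocation of the class mixture
    set.seed(.childSeed(seed, 5L))
    classLabels <- character(n)
    for (cell in names(config$cells)) {
        idx <- which(cells == cell)
        k <- .allocateCounts(length(idx), config$expression$classProbs[cell, ])
        classLabels[sample(idx)] <- rep(config$expression$classes, k)
    }
    names(classLabels) <- samples

    ## expression
    expression <- simulateExpression(config, classLabels,
                                     setNames(cells, samples),
                                     seed = .childSeed(seed, 6L))

    meta <- data.frame(
        sample_id = samples, treatment = treatment, response = response,
        pfs_months = pfs, os_months = osObs,
        pfs_event = 1L, os_event = as.integer(!cens),
        subtype = as.character(classLabels), mgmt = mgmt,
        stringsAsFactors = FALSE)

    acgh <- AcghExperiment(lr, cm, purity = purity, copyNumber = cnm,
                           colData = DataFrame(treatment = treatment,
                                               response = response,
                                               cell = cells))
    list(acgh = acgh, expression = expression, metadata = meta,
         geneSets = metadata(expression)$geneSets,
         truth = list(carriers = carriers, classLabels = classLabels,
                      purity = setNames(purity, samples),
                      events = ev, config = config))
}
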