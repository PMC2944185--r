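## Shared fixtures, built in code. The default-size called cohort is
## expensive (~10 s), so it is simulated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## default study-size cohort, segmented, with stats and five-state calls
calledCohort <- function() {
    if (is.null(.fixtures$cohort)) {
        sim <- simulateCohort(simulationConfig())
        ae <- segmentProfiles(sim$acgh)
        ae <- suppressWarnings(estimateProfileStats(ae))
        ae <- suppressWarnings(callAberrations(ae))
        .fixtures$cohort <- list(sim = sim, ae = ae)
    }
    .fixtures$cohort
}

## small clone map of adjacent, non-overlapping 1 Mb clones
tinyCloneMap <- function(nPerChrom = 50L, chroms = c("chr1", "chr2"),
                         width = 1e6) {
    df <- do.call(rbind, lapply(chroms, function(ch)
        data.frame(chrom = ch,
                   start = (seq_len(nPerChrom) - 1) * width,
                   end = seq_len(nPerChrom) * width)))
    ids <- sprintf("CL%03d", seq_len(nrow(df)))
    sl <- setNames(rep(nPerChrom * width, length(chroms)), chroms)
    CloneMap(ids, df$chrom, df$start, df$end, zeroBased = TRUE,
             seqlengths = sl)
}

## noiseless mixture-model profile on a tiny map: chr1 neutral, chr2 with a
## planted event of the given tumor copy number over clones 11..30
noiselessProfile <- function(R, cn, nPerChrom = 50L) {
    cm <- tinyCloneMap(nPerChrom)
    cnv <- rep(2L, length(cm))
    idx <- nPerChrom + 11:30
    cnv[idx] <- as.integer(cn)
    lr <- log2((R * cnv + (1 - R) * 2) / 2)
    list(cloneMap = cm, lratio = setNames(lr, names(cm)), cn = cnv,
         eventClones = idx)
}

## independent brute-force Ward (Lance-Williams, ward.D convention) used as
## a merge-order oracle for small n
bruteWard <- function(D) {
    n <- nrow(D)
    active <- seq_len(n)
    sizes <- rep(1, n)
    members <- as.list(seq_len(n))
    merges <- list()
    d <- D
    while (length(active) > 1L) {
        best <- c(Inf, NA, NA)
        for (ii in seq_along(active)) for (jj in seq_along(active)) {
            if (jj <= ii) next
            i <- active[ii]; j <- active[jj]
            if (d[i, j] < best[1] - 1e-12) best <- c(d[i, j], i, j)
        }
        i <- best[2]; j <- best[3]
        merges[[length(merges) + 1L]] <- list(height = best[1],
                                              members = sort(c(members[[i]],
                                                               members[[j]])))
        for (k in active) {
            if (k == i || k == j) next
            d[i, k] <- d[k, i] <-
                ((sizes[i] + sizes[k]) * d[i, k] +
                 (sizes[j] + sizes[k]) * d[j, k] -
                 sizes[k] * d[i, j]) / (sizes[i] + sizes[j] + sizes[k])
        }
        members[[i]] <- sort(c(members[[i]], members[[j]]))
        sizes[i] <- sizes[i] + sizes[j]
        active <- setdiff(active, j)
    }
    merges
}

## exhaustive minimal-cost segmentation by bitmask enumeration (oracle)
bruteSegmentCost <- function(y, penalty) {
    n <- length(y)
    best <- Inf
    for (mask in 0:(2^(n - 1) - 1)) {
        bounds <- c(0, which(bitwAnd(mask, 2^(0:(n - 2))) > 0), n)
        cost <- penalty * (length(bounds) - 1)
        for (b in seq_len(length(bounds) - 1)) {
            seg <- y[(bounds[b] + 1):bounds[b + 1]]
            cost <- cost + sum((seg - mean(seg))^2)
        }
        if (cost < best) best <- cost
    }
    best
}
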