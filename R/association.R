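## Differential genomics between responder groups: per-clone event
## frequencies, and per-region Fisher tests with Benjamini-Hochberg
## adjustment.

.checkGroups <- function(groups, samples) {
    if (is.null(names(groups)))
        stop("'groups' must be a named vector (names = sample identifiers)")
    miss <- setdiff(samples, names(groups))
    if (length(miss) > 0L)
        stop("sample(s) without group assignment: ",
             paste(head(miss, 3L), collapse = ", "))
    g <- factor(as.character(groups[samples]))
    if (any(table(g) == 0L) || nlevels(g) < 2L)
        stop("every group must contain at least one sample")
    g
}

#' Per-clone event frequencies by group
#'
#' For every clone, the fraction of samples in each group carrying the
#' requested event. Samples with a missing call at a clone are excluded from
#' that clone's denominator.
#'
#' @param x an [AcghExperiment-class] with a `calls` assay.
#' @param groups named vector mapping sample identifiers to group labels.
#' @param event one of `"gain"`, `"loss"`, `"amp"`, `"homdel"`.
#' @return Numeric matrix, clones x groups.
#' @export
cloneFrequencyTable <- function(x, groups, event) {
    event <- match.arg(event, .EVENT_TYPES)
    calls <- aberrationCalls(x)
    g <- .checkGroups(groups, colnames(calls))
    hit <- !is.na(calls) & calls == event
    obs <- !is.na(calls)
    out <- vapply(levels(g), function(lv) {
        cols <- which(g == lv)
        rowSums(hit[, cols, drop = FALSE]) /
            pmax(rowSums(obs[, cols, drop = FALSE]), 1L)
    }, numeric(nrow(calls)))
    rownames(out) <- rownames(calls)
    out
}

#' Differential genomic status of regions between two groups
#'
#' For each region (an MCR or a single clone), tests whether the presence of
#' the event differs between the two groups: a sample is event-positive if
#' any of its non-missing clones inside the region carries the event; the
#' 2x2 table (group x presence) is tested with the two-sided Fisher exact
#' test and q-values are computed across all regions tested (one event type
#' per call). A region with the same zero margin in both groups gets p = 1.
#'
#' @param x an [AcghExperiment-class] with a `calls` assay.
#' @param regions a [GenomicRanges::GRanges] of regions to test, e.g. from
#'   [deriveMCRs()] (clones overlapping each region are used).
#' @param groups named vector mapping sample identifiers to exactly two
#'   group labels.
#' @param event one of `"gain"`, `"loss"`, `"amp"`, `"homdel"`.
#' @param alpha significance flag threshold on the raw p-value.
#' @return A data.frame sorted by p-value with one row per region: `chrom`,
#'   `start`, `end`, `event`, per-group counts and frequencies, `p`, `q`,
#'   `significant`. Row order of ties follows genomic position.
#' @export
differentialRegions <- function(x, regions, groups, event, alpha = 0.05) {
    event <- match.arg(event, .EVENT_TYPES)
    calls <- aberrationCalls(x)
    g <- .checkGroups(groups, colnames(calls))
    if (nlevels(g) != 2L)
        stop("differentialRegions() requires exactly two groups")
    if (length(regions) == 0L)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), event = character(),
                          n1 = integer(), n2 = integer(),
                          freq1 = numeric(), freq2 = numeric(),
                          p = numeric(), q = numeric(),
                          significant = logical()))
    ov <- findOverlaps(regions, rowRanges(x), ignore.strand = TRUE)
    lv <- levels(g)
    rows <- lapply(seq_along(regions), function(i) {
        idx <- subjectHits(ov)[queryHits(ov) == i]
        if (length(idx) == 0L)
            stop("region ", i, " overlaps no clone of the clone map")
        sub <- calls[idx, , drop = FALSE]
        present <- apply(sub, 2L, function(v) any(v == event, na.rm = TRUE))
        observed <- apply(sub, 2L, function(v) any(!is.na(v)))
        k1 <- sum(present[g == lv[1L] & observed])
        k2 <- sum(present[g == lv[2L] & observed])
        m1 <- sum(g == lv[1L] & observed)
        m2 <- sum(g == lv[2L] & observed)
        tab <- matrix(c(k1, k2, m1 - k1, m2 - k2), 2L)
        p <- if (sum(tab) == 0L || (k1 + k2 == 0L)) 1
             else fisherExact2x2(tab)$p
        data.frame(chrom = as.character(seqnames(regions))[i],
                   start = start(regions)[i], end = end(regions)[i],
                   event = event, n1 = k1, n2 = k2,
                   freq1 = if (m1 > 0L) k1 / m1 else 0,
                   freq2 = if (m2 > 0L) k2 / m2 else 0,
                   p = p, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    names(res)[names(res) == "n1"] <- paste0("n_", lv[1L])
    names(res)[names(res) == "n2"] <- paste0("n_", lv[2L])
    names(res)[names(res) == "freq1"] <- paste0("freq_", lv[1L])
    names(res)[names(res) == "freq2"] <- paste0("freq_", lv[2L])
    res$q <- bhAdjust(res$p)
    res$significant <- res$p < alpha
    res[order(res$p, res$chrom, res$start), , drop = FALSE]
}

#' Clone-level differential testing
#'
#' Convenience wrapper: tests every clone as its own region.
#'
#' @inheritParams differentialRegions
#' @return As [differentialRegions()], one row per clone, with an extra
#'   `clone_id` column.
#' @export
differentialClones <- function(x, groups, event, alpha = 0.05) {
    regions <- granges(rowRanges(x))
    res <- differentialRegions(x, regions, groups, event, alpha)
    ## regions are in clone order, so recover ids by genomic match
    key <- paste(res$chrom, res$start, res$end)
    cm <- rowRanges(x)
    cloneKey <- paste(as.character(seqnames(cm)), start(cm), end(cm))
    res$clone_id <- names(cm)[match(key, cloneKey)]
    res
}
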