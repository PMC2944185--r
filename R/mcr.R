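## Minimal common regions: aggregate one event type's per-sample aberrant
## intervals into maximal runs of constant supporting-sample set.

.EVENT_TYPES <- c("gain", "loss", "amp", "homdel")

#' Per-sample aberrant intervals of one event type
#'
#' Collapses each sample's per-clone calls into clone-bounded intervals: one
#' interval per maximal run of clones with the requested status, spanning
#' the first clone's start to the last clone's end.
#'
#' @param x an [AcghExperiment-class] with a `calls` assay.
#' @param event one of `"gain"`, `"loss"`, `"amp"`, `"homdel"`.
#' @param samples optional subset of sample identifiers.
#' @return A data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based closed, clone-bounded).
#' @export
callsToIntervals <- function(x, event, samples = colnames(x)) {
    event <- match.arg(event, .EVENT_TYPES)
    calls <- aberrationCalls(x)[, samples, drop = FALSE]
    cm <- cloneMap(x)
    chrom <- as.character(seqnames(cm))
    out <- list()
    for (s in colnames(calls)) {
        hit <- !is.na(calls[, s]) & calls[, s] == event
        if (!any(hit)) next
        for (ch in unique(chrom[hit])) {
            idx <- which(chrom == ch)
            r <- rle(hit[idx])
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            keep <- which(r$values)
            out[[length(out) + 1L]] <- data.frame(
                sample = s, chrom = ch,
                start = start(cm)[idx[starts[keep]]],
                end = end(cm)[idx[ends[keep]]],
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(sample = character(), chrom = character(),
                          start = integer(), end = integer()))
    do.call(rbind, out)
}

## Sweep one chromosome's intervals into maximal constant-support runs.
## Atoms falling entirely between clones (possible on sparsely tiled
## regions, where the gap support is the intersection of the flanking
## clones' supports) carry no measurement and are dropped; region
## coordinates are clamped to the clones they cover.
.sweepChromosome <- function(ints, cloneStart, cloneEnd, minRecurrence) {
    ## work in half-open coordinates [start, end + 1)
    bps <- sort(unique(c(ints$start, ints$end + 1)))
    if (length(bps) < 2L) return(NULL)
    aStart <- bps[-length(bps)]
    aEnd <- bps[-1L] - 1L                      # back to closed
    hasClone <- vapply(seq_along(aStart), function(i)
        any(cloneStart <= aEnd[i] & cloneEnd >= aStart[i]), logical(1L))
    aStart <- aStart[hasClone]; aEnd <- aEnd[hasClone]
    if (length(aStart) == 0L) return(NULL)
    support <- lapply(seq_along(aStart), function(i)
        sort(unique(ints$sample[ints$start <= aStart[i] &
                                ints$end >= aEnd[i]])))
    key <- vapply(support, paste, character(1L), collapse = ",")
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    res <- list()
    for (k in seq_along(r$values)) {
        sup <- support[[starts[k]]]
        if (length(sup) < minRecurrence) next
        ## clone-bounded coordinates of the run
        covered <- cloneStart <= aEnd[ends[k]] & cloneEnd >= aStart[starts[k]]
        res[[length(res) + 1L]] <- data.frame(
            start = max(aStart[starts[k]], min(cloneStart[covered])),
            end = min(aEnd[ends[k]], max(cloneEnd[covered])),
            nSupport = length(sup),
            support = paste(sup, collapse = ","),
            stringsAsFactors = FALSE)
    }
    if (length(res) == 0L) NULL else do.call(rbind, res)
}

#' @describeIn deriveMCRs derive minimal common regions of one event type
#'   from the aberration calls of an [AcghExperiment-class].
#'
#' Sweep construction: per chromosome, all interval breakpoints cut the axis
#' into atomic intervals; each atomic interval's supporting-sample set is
#' computed, and an MCR is a maximal run of atomic intervals with an
#' identical supporting set whose recurrence reaches `minRecurrence`.
#' Coordinates are clone-bounded. Adjacent regions with different supporting
#' sets are deliberately not merged (they are distinct events). The result
#' is invariant to sample order.
#'
#' @param x an [AcghExperiment-class] with a `calls` assay.
#' @param event one of `"gain"`, `"loss"`, `"amp"`, `"homdel"`.
#' @param minRecurrence minimum number of supporting samples (default 2).
#' @param samples optional subset of samples to aggregate over.
#' @return A [GenomicRanges::GRanges] of MCRs with metadata columns `event`,
#'   `nSupport`, `support` (comma-separated sample ids); empty when no
#'   region recurs.
#' @export
setMethod("deriveMCRs", "AcghExperiment",
          function(x, event, minRecurrence = 2L, samples = colnames(x)) {
    event <- match.arg(event, .EVENT_TYPES)
    stopifnot(minRecurrence >= 1L)
    ints <- callsToIntervals(x, event, samples)
    empty <- GRanges()
    mcols(empty) <- DataFrame(event = character(), nSupport = integer(),
                              support = character())
    if (nrow(ints) == 0L) return(empty)
    cm <- cloneMap(x)
    cmChrom <- as.character(seqnames(cm))
    out <- list()
    for (ch in sort(unique(ints$chrom))) {
        onCh <- cmChrom == ch
        sw <- .sweepChromosome(ints[ints$chrom == ch, , drop = FALSE],
                               start(cm)[onCh], end(cm)[onCh],
                               minRecurrence)
        if (is.null(sw)) next
        sw$chrom <- ch
        out[[length(out) + 1L]] <- sw
    }
    if (length(out) == 0L) return(empty)
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(event = event, nSupport = df$nSupport,
                           support = df$support)
    gr <- GenomeInfoDb::sortSeqlevels(gr)
    GenomicRanges::sort(gr, ignore.strand = TRUE)
})
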