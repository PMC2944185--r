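## Piecewise-constant smoothing of per-clone log2 ratios: exact least-squares
## dynamic program with a BIC-like per-segment penalty, run independently per
## chromosome.

#' Exact least-squares segmentation of a 1-d signal
#'
#' Minimizes `sum of squared residuals + penalty * (number of segments)` over
#' all segmentations by dynamic programming (optimal partitioning; exact, not
#' heuristic). Missing values are dropped from the fit and remain missing in
#' the smoothed output.
#'
#' The default penalty is `2 * sigma^2 * log(n)` with the noise scale
#' estimated robustly from first differences,
#' `sigma = 1.4826 * median(|diff(x)|) / sqrt(2)`; a small positive floor
#' keeps the program well defined on noiseless signals (where the minimal
#' number of segments attaining zero residual is selected).
#'
#' @param x numeric vector (one chromosome's clone ratios, in genomic
#'   order); may contain NA.
#' @param penalty per-segment penalty; `NULL` for the default above.
#' @return A list: `smoothed` (same length as `x`, segment means, NA where
#'   input was missing), `segments` (data.frame with `firstIndex`,
#'   `lastIndex`, `nClones`, `mean` over the non-missing positions),
#'   `penalty` (value used).
#' @examples
#' segmentSignal(c(rep(0, 20), rep(-1, 20)))$segments
#' @export
segmentSignal <- function(x, penalty = NULL) {
    obs <- which(!is.na(x))
    n <- length(obs)
    smoothed <- rep(NA_real_, length(x))
    if (n == 0L)
        return(list(smoothed = smoothed,
                    segments = data.frame(firstIndex = integer(),
                                          lastIndex = integer(),
                                          nClones = integer(),
                                          mean = numeric()),
                    penalty = penalty %||% NA_real_))
    y <- x[obs]
    if (is.null(penalty)) {
        sigma <- if (n >= 2L) 1.4826 * median(abs(diff(y))) / sqrt(2) else 0
        penalty <- max(2 * sigma^2 * log(max(n, 2L)), 1e-8)
    }
    if (penalty <= 0) stop("'penalty' must be positive")
    cs <- c(0, cumsum(y))
    cs2 <- c(0, cumsum(y^2))
    F <- c(0, rep(Inf, n))        # F[j+1] = optimal cost of y[1..j]
    back <- integer(n)            # start index of last segment ending at j
    for (j in seq_len(n)) {
        i <- seq_len(j)           # candidate segment starts
        len <- j - i + 1
        segCost <- cs2[j + 1L] - cs2[i] - (cs[j + 1L] - cs[i])^2 / len
        tot <- F[i] + segCost + penalty
        best <- which.min(tot)    # ties: smallest start (longest last segment)
        F[j + 1L] <- tot[best]
        back[j] <- best
    }
    ## backtrack
    bounds <- integer(0)
    j <- n
    while (j > 0L) {
        i <- back[j]
        bounds <- c(i, bounds)
        j <- i - 1L
    }
    starts <- bounds
    ends <- c(bounds[-1L] - 1L, n)
    means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1)
    for (k in seq_along(starts))
        smoothed[obs[starts[k]:ends[k]]] <- means[k]
    list(smoothed = smoothed,
         segments = data.frame(firstIndex = obs[starts],
                               lastIndex = obs[ends],
                               nClones = ends - starts + 1L,
                               mean = means),
         penalty = penalty)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn segmentProfiles segment every sample of an
#'   [AcghExperiment-class], per chromosome, adding a `smoothed` assay and
#'   recording the per-sample segment tables in
#'   `metadata(x)$segments`.
#' @param x an [AcghExperiment-class].
#' @param penalty per-segment penalty passed to [segmentSignal()] (`NULL`
#'   for the robust default, estimated per sample and chromosome).
#' @return The input object with a `smoothed` assay and segment tables in
#'   `metadata(x)$segments` (one data.frame per sample with columns `chrom`,
#'   `firstIndex`, `lastIndex`, `nClones`, `mean`, `start`, `end`).
#' @export
setMethod("segmentProfiles", "AcghExperiment", function(x, penalty = NULL) {
    lr <- lratio(x)
    cm <- rowRanges(x)
    chrom <- as.character(seqnames(cm))
    chroms <- unique(chrom)
    sm <- matrix(NA_real_, nrow(lr), ncol(lr), dimnames = dimnames(lr))
    segTables <- vector("list", ncol(lr))
    names(segTables) <- colnames(lr)
    for (s in seq_len(ncol(lr))) {
        segs <- list()
        for (ch in chroms) {
            idx <- which(chrom == ch)
            if (sum(!is.na(lr[idx, s])) < 2L && length(idx) >= 1L)
                warning("chromosome ", ch, " of sample ", colnames(lr)[s],
                        " has < 2 usable clones; single segment",
                        call. = FALSE)
            fit <- segmentSignal(lr[idx, s], penalty = penalty)
            sm[idx, s] <- fit$smoothed
            if (nrow(fit$segments) > 0L) {
                sg <- fit$segments
                sg$chrom <- ch
                sg$start <- start(cm)[idx[sg$firstIndex]]
                sg$end <- end(cm)[idx[sg$lastIndex]]
                sg$firstIndex <- idx[sg$firstIndex]
                sg$lastIndex <- idx[sg$lastIndex]
                segs[[length(segs) + 1L]] <- sg
            }
        }
        segTables[[s]] <- do.call(rbind, segs) %||%
            data.frame(firstIndex = integer(), lastIndex = integer(),
                       nClones = integer(), mean = numeric(),
                       chrom = character(), start = integer(),
                       end = integer())
    }
    assay(x, "smoothed") <- sm
    metadata(x)$segments <- segTables
    x
})
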