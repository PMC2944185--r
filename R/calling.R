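## Five-state aberration calling: replicate averaging, profile mode/robust
## SD, tumor-cell-rate estimation, and thresholding of smoothed log2 ratios.
##
## Copy-number model (two-population mixture): a clone with tumor copy
## number cn in a sample of tumor-cell rate R has expected log2 ratio
##   log2((R * cn + 2 * (1 - R)) / 2).
## Homozygous deletions therefore sit at log2(1 - R), single-copy losses at
## log2(1 - R/2), single-copy gains at log2(1 + R/2), and the amplicon
## threshold log2(1 + 1.5 R) corresponds to the 5-copy boundary.

#' Calling parameters
#'
#' @param sdMultiplier gain/loss threshold in robust-SD units around the
#'   profile mode (default 1).
#' @param ampFactor amplicon factor: amplicons are called above
#'   `log2(1 + ampFactor * R)` (default 1.5, the 5-copy boundary).
#' @param tolerance inclusive slack on the homdel/amp thresholds; the
#'   noiseless homdel level equals its threshold exactly under the mixture
#'   model, so the comparison is inclusive within this tolerance.
#' @param rTCClamp admissible range for the estimated tumor-cell rate.
#' @param rTCDefault fallback rate when a profile shows no usable aberrant
#'   segment.
#' @param noiseGuard multiplier of the robust residual noise used to relax
#'   the homdel/amp thresholds under noise (see [callAberrations()]); 0
#'   disables the guard. Exactly inert on noiseless data.
#' @param minAberrantFraction minimum fraction of clones that a candidate
#'   aberration class must cover for it to drive the tumor-cell-rate
#'   estimate (guards against latching onto small spurious segments;
#'   single-copy events in this tumor type are chromosome-scale).
#' @return A list of validated calling parameters.
#' @export
callingParameters <- function(sdMultiplier = 1.0, ampFactor = 1.5,
                              tolerance = 1e-9, rTCClamp = c(0.1, 0.95),
                              rTCDefault = 0.7, noiseGuard = 1.5,
                              minAberrantFraction = 0.02) {
    stopifnot(sdMultiplier > 0, ampFactor > 0, tolerance >= 0,
              length(rTCClamp) == 2L, rTCClamp[1L] > 0, rTCClamp[2L] < 1,
              rTCClamp[1L] < rTCClamp[2L],
              rTCDefault >= rTCClamp[1L], rTCDefault <= rTCClamp[2L],
              noiseGuard >= 0, minAberrantFraction >= 0,
              minAberrantFraction < 1)
    list(sdMultiplier = sdMultiplier, ampFactor = ampFactor,
         tolerance = tolerance, rTCClamp = rTCClamp,
         rTCDefault = rTCDefault, noiseGuard = noiseGuard,
         minAberrantFraction = minAberrantFraction)
}

#' Average replicate spots per clone
#'
#' @param spotTable data.frame with columns `clone_id`, `replicate_index`,
#'   `log2_ratio` (a clone may have any number of replicates >= 1).
#' @param cloneMap a [CloneMap-class]; every clone in the spot table must be
#'   mapped.
#' @return Named numeric vector of per-clone mean log2 ratios over the
#'   non-missing replicates, aligned to `cloneMap` order; a clone whose
#'   replicates are all missing (or absent from the table) is NA.
#' @export
averageReplicates <- function(spotTable, cloneMap) {
    need <- c("clone_id", "replicate_index", "log2_ratio")
    if (!all(need %in% colnames(spotTable)))
        stop("spot table must have columns: ", paste(need, collapse = ", "))
    if (any(spotTable$replicate_index < 1))
        stop("replicate_index must be >= 1")
    unknown <- setdiff(unique(spotTable$clone_id), names(cloneMap))
    if (length(unknown) > 0L)
        stop("clone absent from the clone map: '", unknown[1L], "'")
    means <- tapply(spotTable$log2_ratio, spotTable$clone_id,
                    function(v) {
                        v <- v[!is.na(v)]
                        if (length(v) == 0L) NA_real_ else mean(v)
                    })
    out <- setNames(rep(NA_real_, length(cloneMap)), names(cloneMap))
    out[names(means)] <- as.numeric(means)
    out
}

#' Mode and robust SD of a smoothed profile
#'
#' The mode is the argmax of a Gaussian kernel density (Silverman's
#' rule-of-thumb bandwidth, 512-point grid over the data range), refined by
#' snapping to the nearest observed value so that quantized
#' piecewise-constant profiles recenter exactly. The scale is
#' `1.4826 * median(|x - mode|)` (MAD about the mode), robust to large
#' aberrant fractions.
#'
#' @param x numeric vector of smoothed per-clone log2 ratios (NA dropped);
#'   at least 10 non-missing values unless all are equal.
#' @return A list with `mode` and `sd`.
#' @export
profileModeSD <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) stop("no non-missing values")
    if (diff(range(x)) == 0)
        return(list(mode = x[1L], sd = 0))
    if (length(x) < 10L)
        stop("need >= 10 non-missing smoothed values")
    d <- density(x, bw = "nrd0", n = 512L, from = min(x), to = max(x))
    peak <- d$x[which.max(d$y)]
    mode <- x[which.min(abs(x - peak))]
    list(mode = mode, sd = 1.4826 * median(abs(x - mode)))
}

#' Estimate the tumor-cell rate from segment displacements
#'
#' Each aberrant segment's displacement from the profile mode is inverted
#' under the mixture model as if it were a single-copy event: a loss segment
#' at mean `m` implies `R = 2 (1 - 2^(m - mode))`, a gain segment implies
#' `R = 2 (2^(m - mode) - 1)`. Implied rates outside the admissible clamp
#' are discarded (a homozygous deletion read as a single-copy loss implies
#' `2R`, outside the clamp for realistic purities), and a candidate class is
#' only trusted when its surviving segments cover at least
#' `minAberrantFraction` of the clones (single-copy events in glioblastoma
#' are chromosome-scale; small spurious segments must not drive the
#' estimate). The estimate is the segment-length-weighted median of the
#' surviving implied rates, preferring losses, then gains; failing both, a
#' deep-loss fallback inverts segments at the homozygous-deletion level
#' (`R = 1 - 2^(m - mode)` for segments displaced below the single-copy
#' band); failing everything the default rate is returned with a warning.
#'
#' @param segments data.frame of segments with columns `mean` and `nClones`
#'   (as produced by [segmentSignal()]/[segmentProfiles()]).
#' @param mode,sd profile mode and robust SD from [profileModeSD()].
#' @param params [callingParameters()].
#' @param residSd robust per-clone residual noise of the profile; used only
#'   to propagate the estimate's uncertainty into `seLog` (0 for noiseless
#'   data).
#' @return A list with `rTC` (clamped estimate), `source`
#'   (`"loss"`, `"gain"`, `"homdel"` or `"default"`), and `seLog`, the
#'   standard error of the homozygous-deletion threshold `log2(1 - rTC)`
#'   implied by the estimate's sampling noise (log2 units; exactly 0 when
#'   `residSd = 0`). Near-unit purity the threshold is steeply sensitive to
#'   the rate (`d log2(1-R) / dR = -1 / ((1-R) ln 2)`), so downstream
#'   calling widens its detection margin by this amount.
#' @export
estimateTumorCellRate <- function(segments, mode, sd,
                                  params = callingParameters(),
                                  residSd = 0) {
    lo <- params$rTCClamp[1L]; hi <- params$rTCClamp[2L]
    m <- segments$mean - mode
    w <- segments$nClones
    minW <- params$minAberrantFraction * sum(w)
    pickIf <- function(r, w, source) {
        ok <- r >= lo & r <= hi
        if (!any(ok) || sum(w[ok]) < minW) return(NULL)
        rHat <- min(max(.weightedMedian(r[ok], w[ok]), lo), hi)
        seM <- residSd / sqrt(sum(w[ok]))
        ## |d log2(1-R) / d m|: inversion slope x threshold slope
        fac <- if (source == "loss") 2 * (1 - rHat / 2) / (1 - rHat)
               else 2 * (1 + rHat / 2) / (1 - rHat)
        list(rTC = rHat, source = source, seLog = fac * seM)
    }
    lossIdx <- which(m < -params$sdMultiplier * sd)
    est <- pickIf(2 * (1 - 2^(m[lossIdx])), w[lossIdx], "loss")
    if (!is.null(est)) return(est)
    gainIdx <- which(m > params$sdMultiplier * sd)
    est <- pickIf(2 * (2^(m[gainIdx]) - 1), w[gainIdx], "gain")
    if (!is.null(est)) return(est)
    ## deep losses: segments below the single-copy band at any admissible
    ## purity are homozygous-deletion levels; invert log2(1 - R) directly.
    ## These are focal by nature, so no minimum-fraction gate (2+ clones).
    deepIdx <- which(m < log2(1 - hi / 2))
    rDeep <- 1 - 2^(m[deepIdx])
    okD <- rDeep >= lo & rDeep <= hi & w[deepIdx] >= 2L
    if (any(okD))
        return(list(rTC = min(max(.weightedMedian(rDeep[okD],
                                                  w[deepIdx][okD]),
                                  lo), hi),
                    source = "homdel",
                    seLog = residSd / sqrt(sum(w[deepIdx][okD]))))
    warning("no aberrant segment usable for tumor-cell rate estimation; ",
            "using default ", params$rTCDefault, call. = FALSE)
    list(rTC = params$rTCDefault, source = "default", seLog = 0)
}

## Weighted median: smallest value whose cumulative weight reaches half the
## total. Deterministic under ties.
.weightedMedian <- function(x, w) {
    o <- order(x)
    x <- x[o]; w <- w[o]
    cw <- cumsum(w)
    x[which(cw >= sum(w) / 2)[1L]]
}

#' Aberration-calling thresholds
#'
#' Thresholds on the mode-recentered smoothed log2 ratio `v`:
#' homdel at `log2(1 - rEff)`, loss at `-sdMultiplier * sd`, gain at
#' `+sdMultiplier * sd`, amp at `log2(1 + ampFactor * rEff)`, where the
#' effective rate `rEff = 1 - (1 - rTC) * 2^(noiseGuard * residSd)` relaxes
#' the homdel/amp thresholds by the estimated residual noise (a detection
#' margin; `residSd = 0`, e.g. noiseless data, gives `rEff = rTC` and the
#' exact closed-form thresholds).
#'
#' @param rTC estimated tumor-cell rate.
#' @param sd robust SD of the smoothed profile.
#' @param params [callingParameters()].
#' @param residSd robust per-clone residual noise estimate (0 disables the
#'   guard).
#' @param rTCSeLog standard error of the homdel threshold implied by the
#'   rate estimate (`seLog` from [estimateTumorCellRate()]); widens the
#'   margin the same way.
#' @return Named vector with elements `homdel`, `loss`, `gain`, `amp`.
#' @examples
#' aberrationThresholds(0.8, 0.05)[c("homdel", "amp")]
#' # -2.321928, 1.137504
#' @export
aberrationThresholds <- function(rTC, sd, params = callingParameters(),
                                 residSd = 0, rTCSeLog = 0) {
    rEff <- 1 - (1 - rTC) * 2^(params$noiseGuard * (residSd + rTCSeLog))
    rEff <- min(max(rEff, params$rTCClamp[1L]), params$rTCClamp[2L])
    c(homdel = log2(1 - rEff),
      loss = -params$sdMultiplier * sd,
      gain = params$sdMultiplier * sd,
      amp = log2(1 + params$ampFactor * rEff))
}

#' Call five aberration states from smoothed values
#'
#' On the recentered value `v = smoothed - mode`: homdel if
#' `v <= homdel threshold + tolerance`; else amp if
#' `v >= amp threshold - tolerance`; else loss/gain outside
#' `mode +/- sdMultiplier * sd`; else neutral. Homdel/amp comparisons are
#' inclusive because the noiseless event levels equal the thresholds exactly
#' under the mixture model. With `sd = 0` the gain/loss thresholds are
#' degenerate: only homdel, amp and neutral are callable (with a warning).
#'
#' @param smoothed numeric vector of smoothed log2 ratios (NA preserved).
#' @param mode,sd profile statistics from [profileModeSD()].
#' @param rTC estimated tumor-cell rate.
#' @param params [callingParameters()].
#' @param residSd robust residual noise estimate (see
#'   [aberrationThresholds()]).
#' @param rTCSeLog threshold standard error from the rate estimate (see
#'   [aberrationThresholds()]).
#' @return Character vector of states in
#'   `c("homdel", "loss", "neutral", "gain", "amp")`, NA where input is NA.
#' @export
callStates <- function(smoothed, mode, sd, rTC,
                       params = callingParameters(), residSd = 0,
                       rTCSeLog = 0) {
    thr <- aberrationThresholds(rTC, sd, params, residSd, rTCSeLog)
    tol <- params$tolerance
    if (sd == 0)
        warning("sd = 0: gain/loss thresholds degenerate; only homdel, amp ",
                "and neutral are callable", call. = FALSE)
    v <- smoothed - mode
    st <- rep(NA_character_, length(v))
    ok <- !is.na(v)
    st[ok] <- "neutral"
    if (sd > 0) {
        st[ok & v < thr[["loss"]]] <- "loss"
        st[ok & v > thr[["gain"]]] <- "gain"
    }
    st[ok & v >= thr[["amp"]] - tol] <- "amp"
    st[ok & v <= thr[["homdel"]] + tol] <- "homdel"
    st
}

#' @describeIn estimateProfileStats compute per-sample mode, robust SD,
#'   residual noise and tumor-cell-rate estimate of a segmented
#'   [AcghExperiment-class], storing them in `colData`.
#' @param x an [AcghExperiment-class] processed by [segmentProfiles()].
#' @param params [callingParameters()].
#' @export
setMethod("estimateProfileStats", "AcghExperiment",
          function(x, params = callingParameters()) {
    sm <- smoothedRatio(x)
    lr <- lratio(x)
    segTables <- metadata(x)$segments
    if (is.null(segTables))
        stop("no segment tables; run segmentProfiles() first")
    n <- ncol(sm)
    mode <- sdRob <- rTC <- residSd <- seLog <- numeric(n)
    src <- character(n)
    for (s in seq_len(n)) {
        ms <- profileModeSD(sm[, s])
        mode[s] <- ms$mode; sdRob[s] <- ms$sd
        res <- lr[, s] - sm[, s]
        res <- res[!is.na(res)]
        residSd[s] <- if (length(res) > 0L) 1.4826 * median(abs(res)) else 0
        est <- estimateTumorCellRate(segTables[[s]], ms$mode, ms$sd, params,
                                     residSd = residSd[s])
        rTC[s] <- est$rTC; src[s] <- est$source; seLog[s] <- est$seLog
    }
    colData(x)$mode <- mode
    colData(x)$sdRobust <- sdRob
    colData(x)$residSd <- residSd
    colData(x)$rTC <- rTC
    colData(x)$rTCSource <- src
    colData(x)$rTCSeLog <- seLog
    x
})

#' @describeIn callAberrations call the five aberration states for every
#'   clone and sample of an [AcghExperiment-class] with profile statistics,
#'   adding a `calls` assay; threshold provenance is stored in
#'   `metadata(x)$thresholds`.
#' @param x an [AcghExperiment-class] processed by [segmentProfiles()] and
#'   [estimateProfileStats()].
#' @param params [callingParameters()].
#' @export
setMethod("callAberrations", "AcghExperiment",
          function(x, params = callingParameters()) {
    sm <- smoothedRatio(x)
    cd <- colData(x)
    if (!all(c("mode", "sdRobust", "rTC", "residSd") %in% colnames(cd)))
        stop("profile statistics missing; run estimateProfileStats() first")
    calls <- matrix(NA_character_, nrow(sm), ncol(sm),
                    dimnames = dimnames(sm))
    thrs <- vector("list", ncol(sm))
    names(thrs) <- colnames(sm)
    seLog <- if ("rTCSeLog" %in% colnames(cd)) cd$rTCSeLog else numeric(ncol(sm))
    for (s in seq_len(ncol(sm))) {
        calls[, s] <- callStates(sm[, s], cd$mode[s], cd$sdRobust[s],
                                 cd$rTC[s], params, cd$residSd[s], seLog[s])
        thrs[[s]] <- aberrationThresholds(cd$rTC[s], cd$sdRobust[s], params,
                                          cd$residSd[s], seLog[s])
    }
    assay(x, "calls") <- calls
    metadata(x)$thresholds <- thrs
    metadata(x)$callingParameters <- params
    x
})
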