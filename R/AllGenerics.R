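#' @include GBMprofiler-package.R
NULL

#' @export
setGeneric("cloneMap", function(x, ...) standardGeneric("cloneMap"))

#' @export
setGeneric("lratio", function(x, ...) standardGeneric("lratio"))

#' @export
setGeneric("smoothedRatio", function(x, ...) standardGeneric("smoothedRatio"))

#' @export
setGeneric("aberrationCalls", function(x, ...) standardGeneric("aberrationCalls"))

#' @export
setGeneric("profileStats", function(x, ...) standardGeneric("profileStats"))

#' @export
setGeneric("truePurity", function(x, ...) standardGeneric("truePurity"))

#' @export
setGeneric("trueCopyNumber", function(x, ...) standardGeneric("trueCopyNumber"))

#' Segment copy-number profiles
#'
#' Piecewise-constant smoothing of per-clone log2 ratios, per sample and
#' chromosome. See the method for [AcghExperiment-class] objects.
#'
#' @param x object holding profiles to segment.
#' @param ... passed to methods.
#' @export
setGeneric("segmentProfiles", function(x, ...) standardGeneric("segmentProfiles"))

#' Estimate per-sample profile statistics
#'
#' Mode, robust SD, residual noise and tumor-cell-rate estimate of each
#' segmented profile. See the method for [AcghExperiment-class] objects.
#'
#' @param x object holding segmented profiles.
#' @param ... passed to methods.
#' @export
setGeneric("estimateProfileStats", function(x, ...) standardGeneric("estimateProfileStats"))

#' Call five-state copy-number aberrations
#'
#' Classifies every clone as homdel/loss/neutral/gain/amp from its smoothed
#' log2 ratio and the sample's profile statistics. See the method for
#' [AcghExperiment-class] objects and [callStates()] for the rules.
#'
#' @param x object holding segmented profiles with statistics.
#' @param ... passed to methods.
#' @export
setGeneric("callAberrations", function(x, ...) standardGeneric("callAberrations"))

#' Derive minimal common regions
#'
#' Aggregates one event type's per-sample aberrant intervals into maximal
#' constant-support recurrent regions. See the method for
#' [AcghExperiment-class] objects.
#'
#' @param x object holding aberration calls.
#' @param ... passed to methods.
#' @export
setGeneric("deriveMCRs", function(x, ...) standardGeneric("deriveMCRs"))

#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @export
setGeneric("geneUniverse", function(x, ...) standardGeneric("geneUniverse"))
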