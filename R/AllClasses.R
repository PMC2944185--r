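#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- CloneMap

#' CloneMap: genomic positions of array-CGH clones
#'
#' A [GenomicRanges::GRanges] subclass holding the genomic layout of the BAC
#' clones spotted on a CGH array. Names are clone identifiers; ranges may
#' overlap (BAC tiling), but the object is kept in canonical order
#' (chromosome, then start). Coordinates follow the Bioconductor 1-based
#' closed convention internally; conversion from/to 0-based half-open files
#' happens only in [readCloneMap()] / [writeCloneMap()] / [writeSegmentsBED()].
#'
#' @export
setClass("CloneMap", contains = "GRanges")

setValidity("CloneMap", function(object) {
    msg <- character()
    nm <- names(object)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        msg <- c(msg, "all clones must be named by a clone identifier")
    else if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicated clone identifier: '%s'",
                              nm[duplicated(nm)][1L]))
    if (any(width(object) < 1L))
        msg <- c(msg, "clone end must be greater than clone start")
    if (length(object) > 1L &&
        BiocGenerics::is.unsorted(object, ignore.strand = TRUE))
        msg <- c(msg, "clones must be sorted by (chromosome, start)")
    if (length(msg)) msg else TRUE
})

#' Construct a CloneMap
#'
#' @param cloneId character vector of unique clone identifiers.
#' @param chrom chromosome of each clone.
#' @param start,end clone coordinates. With `zeroBased = TRUE` (the file
#'   convention of this package) they are interpreted as 0-based half-open
#'   and converted; with `zeroBased = FALSE` they are 1-based closed.
#' @param zeroBased logical flag giving the coordinate convention of the
#'   input vectors.
#' @param seqlengths optional named vector of chromosome lengths (bp).
#' @return A [CloneMap-class] object in canonical sort order.
#' @examples
#' cm <- CloneMap(c("c1", "c2"), c("chr1", "chr1"), c(0, 670000),
#'                c(150000, 820000))
#' @export
CloneMap <- function(cloneId, chrom, start, end, zeroBased = TRUE,
                     seqlengths = NULL) {
    if (anyDuplicated(cloneId))
        stop("duplicated clone identifier: '",
             cloneId[duplicated(cloneId)][1L], "'")
    start <- as.numeric(start); end <- as.numeric(end)
    if (any(end <= start))
        stop("clone end must be greater than clone start (clone '",
             cloneId[which(end <= start)[1L]], "')")
    if (zeroBased) start <- start + 1
    gr <- GRanges(chrom, IRanges(start = start, end = end))
    names(gr) <- cloneId
    gr <- GenomeInfoDb::sortSeqlevels(gr)
    if (!is.null(seqlengths)) {
        sl <- seqlengths[GenomeInfoDb::seqlevels(gr)]
        GenomeInfoDb::seqlengths(gr) <- sl
    }
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    new("CloneMap", gr)
}

setMethod("show", "CloneMap", function(object) {
    cat("CloneMap with", length(object), "clones on",
        length(GenomeInfoDb::seqlevels(object)), "chromosomes\n")
    callNextMethod()
})

## ---------------------------------------------------------- AcghExperiment

#' AcghExperiment: per-clone log2 ratios and derived copy-number calls
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] subclass for
#' array-CGH cohorts. Rows are clones (with their [CloneMap-class] as
#' `rowRanges`), columns are samples. Assays:
#' \describe{
#'   \item{`lratio`}{normalized log2 ratios (required).}
#'   \item{`cn`}{true integer copy number, simulation truth (optional).}
#'   \item{`smoothed`}{piecewise-constant smoothed log2 ratios, added by
#'     [segmentProfiles()].}
#'   \item{`calls`}{five-state aberration status, added by
#'     [callAberrations()].}
#' }
#' Per-sample statistics (`purity`, `mode`, `sdRobust`, `rTC`, `rTCSource`,
#' `residSd`) live in `colData`.
#'
#' @export
setClass("AcghExperiment", contains = "RangedSummarizedExperiment")

setValidity("AcghExperiment", function(object) {
    msg <- character()
    if (!"lratio" %in% assayNames(object))
        msg <- c(msg, "assay 'lratio' is required")
    if (is.null(rownames(object)) ||
        !identical(rownames(object), names(rowRanges(object))))
        msg <- c(msg, "rownames must equal the clone identifiers of rowRanges")
    if (length(msg)) msg else TRUE
})

#' Construct an AcghExperiment
#'
#' @param lratio numeric matrix of log2 ratios, clones x samples. Row names
#'   must match the clone identifiers of `cloneMap`, in the same order.
#' @param cloneMap a [CloneMap-class].
#' @param purity optional per-sample true tumor-cell rate (simulation truth).
#' @param copyNumber optional integer matrix of true copy numbers.
#' @param colData optional extra per-sample annotation.
#' @return An [AcghExperiment-class].
#' @export
AcghExperiment <- function(lratio, cloneMap, purity = NULL, copyNumber = NULL,
                           colData = NULL) {
    lratio <- as.matrix(lratio)
    if (is.null(rownames(lratio)))
        rownames(lratio) <- names(cloneMap)
    if (!identical(rownames(lratio), names(cloneMap)))
        stop("rownames of 'lratio' must match clone identifiers of 'cloneMap'")
    if (is.null(colnames(lratio)))
        colnames(lratio) <- sprintf("S%03d", seq_len(ncol(lratio)))
    assays <- list(lratio = lratio)
    if (!is.null(copyNumber)) {
        copyNumber <- as.matrix(copyNumber)
        dimnames(copyNumber) <- dimnames(lratio)
        assays$cn <- copyNumber
    }
    cd <- DataFrame(row.names = colnames(lratio))
    if (!is.null(purity)) cd$purity <- as.numeric(purity)
    if (!is.null(colData)) cd <- cbind(cd, DataFrame(colData))
    se <- SummarizedExperiment(assays = assays, rowRanges = cloneMap,
                               colData = cd)
    new("AcghExperiment", se)
}

#' @describeIn AcghExperiment clone map of the experiment.
#' @param x,object an `AcghExperiment`.
#' @export
setMethod("cloneMap", "AcghExperiment", function(x)
    new("CloneMap", granges(rowRanges(x))))

#' @describeIn AcghExperiment matrix of normalized log2 ratios.
#' @export
setMethod("lratio", "AcghExperiment", function(x) assay(x, "lratio"))

#' @describeIn AcghExperiment matrix of smoothed (segmented) log2 ratios.
#' @export
setMethod("smoothedRatio", "AcghExperiment", function(x) {
    if (!"smoothed" %in% assayNames(x))
        stop("no 'smoothed' assay; run segmentProfiles() first")
    assay(x, "smoothed")
})

#' @describeIn AcghExperiment matrix of five-state aberration calls.
#' @export
setMethod("aberrationCalls", "AcghExperiment", function(x) {
    if (!"calls" %in% assayNames(x))
        stop("no 'calls' assay; run callAberrations() first")
    assay(x, "calls")
})

#' @describeIn AcghExperiment per-sample profile statistics (mode, robust sd,
#'   estimated tumor-cell rate and its source, residual noise).
#' @export
setMethod("profileStats", "AcghExperiment", function(x) {
    want <- intersect(c("purity", "mode", "sdRobust", "rTC", "rTCSource",
                        "residSd"), colnames(colData(x)))
    colData(x)[, want, drop = FALSE]
})

#' @describeIn AcghExperiment per-sample true tumor-cell rate (simulation).
#' @export
setMethod("truePurity", "AcghExperiment", function(x) {
    if (!"purity" %in% colnames(colData(x)))
        stop("no 'purity' column in colData")
    setNames(colData(x)$purity, colnames(x))
})

#' @describeIn AcghExperiment matrix of true copy numbers (simulation).
#' @export
setMethod("trueCopyNumber", "AcghExperiment", function(x) {
    if (!"cn" %in% assayNames(x))
        stop("no 'cn' assay (simulation truth)")
    assay(x, "cn")
})

setMethod("show", "AcghExperiment", function(object) {
    cat("AcghExperiment:", nrow(object), "clones x", ncol(object),
        "samples\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    if ("rTC" %in% colnames(colData(object)))
        cat("  estimated tumor-cell rate: [",
            round(min(colData(object)$rTC), 3), ",",
            round(max(colData(object)$rTC), 3), "]\n")
    invisible(NULL)
})

## ------------------------------------------------------- GeneSetCollection

#' GeneSetCollection: named gene sets over a gene universe
#'
#' Named sets of gene symbols together with the universe of annotatable
#' genes. On construction every set is restricted to the universe,
#' de-duplicated, and required to be non-empty.
#'
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "set names must be unique and non-empty")
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "empty gene sets are not allowed")
    if (!all(unlist(object@sets) %in% object@universe))
        msg <- c(msg, "every set must be a subset of the universe")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param universe character vector of all annotatable genes; defaults to the
#'   union of the sets.
#' @return A [GeneSetCollection-class]. Members outside the universe are
#'   dropped; a set left empty after restriction is an error.
#' @export
GeneSetCollection <- function(sets, universe = NULL) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
        stop("gene sets must have unique names")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(universe))
        universe <- sort(unique(unlist(sets)))
    universe <- unique(as.character(universe))
    sets <- lapply(sets, intersect, y = universe)
    empty <- lengths(sets) == 0L
    if (any(empty))
        stop("gene set(s) empty after restriction to the universe: ",
             paste(names(sets)[empty], collapse = ", "))
    new("GeneSetCollection", sets = sets, universe = universe)
}

#' @describeIn GeneSetCollection the named list of gene sets.
#' @param x,object a `GeneSetCollection`.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection the gene universe.
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

setMethod("show", "GeneSetCollection", function(object) {
    cat("GeneSetCollection:", length(object@sets), "sets over a universe of",
        length(object@universe), "genes\n")
    sz <- lengths(object@sets)
    cat("  set sizes: [", min(sz), ",", max(sz), "]\n")
    invisible(NULL)
})

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

## ----------------------------------------------------------- CentroidModel

#' CentroidModel: nearest-centroid expression classifier
#'
#' Per-class mean profiles of standardized (z-scored) expression over a fixed
#' probe list, plus the reference standardization (per-probe mean and sd)
#' used to build them. Built by [buildCentroidClassifier()], applied by
#' [classifyByCentroid()].
#'
#' @export
setClass("CentroidModel",
         representation(centroids = "matrix", refMean = "numeric",
                        refSd = "numeric"))

setValidity("CentroidModel", function(object) {
    msg <- character()
    if (ncol(object@centroids) < 2L)
        msg <- c(msg, "a centroid model needs at least 2 classes")
    if (!all(is.finite(object@centroids)))
        msg <- c(msg, "centroid values must be finite")
    if (!identical(rownames(object@centroids), names(object@refMean)) ||
        !identical(rownames(object@centroids), names(object@refSd)))
        msg <- c(msg, "probe names of centroids and standardization disagree")
    if (length(msg)) msg else TRUE
})

#' @describeIn CentroidModel probe identifiers used by the model.
#' @param object a `CentroidModel`.
#' @export
modelProbes <- function(object) rownames(object@centroids)

#' @describeIn CentroidModel class labels of the model, in model order.
#' @export
modelClasses <- function(object) colnames(object@centroids)

#' @describeIn CentroidModel the probes x classes centroid matrix.
#' @export
centroids <- function(object) object@centroids

setMethod("show", "CentroidModel", function(object) {
    cat("CentroidModel:", ncol(object@centroids), "classes (",
        paste(colnames(object@centroids), collapse = ", "), ") over",
        nrow(object@centroids), "probes\n")
    invisible(NULL)
})
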