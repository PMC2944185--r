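## Readers/writers for the external text formats of the pipeline: TSV
## matrices, clone maps, GMT gene sets, sample metadata, BED5 segment calls.
## All files are UTF-8, "." decimal point, "NA" for missing. Genomic
## coordinates in files (clone map TSV, BED) are 0-based half-open;
## conversion happens here and only here.

#' Read a numeric TSV matrix
#'
#' First row holds sample (column) identifiers, first column probe/clone
#' (row) identifiers, body is numeric with missing values encoded `NA`.
#'
#' @param path file to read.
#' @return Numeric matrix with row and column names in file order.
#' @export
readMatrixTSV <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                     check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2L) stop("matrix file needs an id column and >= 1 sample")
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated row identifier: '", ids[duplicated(ids)][1L], "'")
    cn <- colnames(df)[-1L]
    if (anyDuplicated(cn))
        stop("duplicated column identifier: '", cn[duplicated(cn)][1L], "'")
    body <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    ## "NA" cells arrive as real NAs from the parser; anything else that
    ## fails numeric conversion is a malformed cell
    bad <- which(is.na(num) & !is.na(body) & body != "", arr.ind = TRUE)
    if (nrow(bad) > 0L)
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     body[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                     cn[bad[1L, 2L]]))
    dimnames(num) <- list(ids, cn)
    num
}

#' Write a numeric TSV matrix
#'
#' Inverse of [readMatrixTSV()]: round-trips within 1e-12 (full double
#' precision is written).
#'
#' @param x numeric matrix with dimnames.
#' @param path output file.
#' @param idColumn header of the identifier column.
#' @export
writeMatrixTSV <- function(x, path, idColumn = "id") {
    stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
    df <- data.frame(rownames(x), format(x, digits = 17, trim = TRUE,
                                         scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c(idColumn, colnames(x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a clone map TSV
#'
#' Expected columns: `clone_id`, `chrom`, `start`, `end`. File coordinates
#' are 0-based half-open unless `oneBased = TRUE`, in which case they are
#' 1-based closed and converted at parse time.
#'
#' @param path file to read.
#' @param oneBased set to `TRUE` for 1-based closed input coordinates.
#' @return A [CloneMap-class].
#' @export
readCloneMap <- function(path, oneBased = FALSE) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("clone_id", "chrom", "start", "end")
    if (!all(need %in% colnames(df)))
        stop("clone map must have columns: ", paste(need, collapse = ", "))
    CloneMap(df$clone_id, df$chrom, df$start, df$end,
             zeroBased = !oneBased)
}

#' Write a clone map TSV (0-based half-open)
#'
#' @param cloneMap a [CloneMap-class].
#' @param path output file.
#' @export
writeCloneMap <- function(cloneMap, path) {
    df <- data.frame(clone_id = names(cloneMap),
                     chrom = as.character(seqnames(cloneMap)),
                     start = start(cloneMap) - 1L,
                     end = end(cloneMap))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then the member genes. Duplicate members within a
#' set are de-duplicated; duplicate set names and lines with fewer than
#' three fields are errors.
#'
#' @param path GMT file.
#' @param universe optional gene universe; defaults to the union of members.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path, universe = NULL) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty GMT file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short) > 0L)
        stop("GMT line ", short[1L], " has fewer than 3 fields")
    nm <- vapply(fields, `[[`, character(1L), 1L)
    if (anyDuplicated(nm))
        stop("duplicated gene set name: '", nm[duplicated(nm)][1L], "'")
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    names(sets) <- nm
    if (any(lengths(sets) == 0L))
        stop("empty gene set: '", nm[lengths(sets) == 0L][1L], "'")
    GeneSetCollection(sets, universe = universe)
}

#' Write gene sets in GMT format
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @export
writeGMT <- function(gsc, path, descriptions = NULL) {
    sets <- geneSets(gsc)
    if (is.null(descriptions)) descriptions <- names(sets)
    lines <- mapply(function(nm, d, s)
        paste(c(nm, d, s), collapse = "\t"),
        names(sets), descriptions, sets)
    writeLines(lines, path, useBytes = FALSE)
    invisible(path)
}

.TREATMENTS <- c("RT", "CT")
.RESPONSES <- c("responder", "nonresponder", "unassigned")

#' Read sample metadata TSV
#'
#' Required columns: `sample_id`, `treatment` (RT/CT), `response`
#' (responder/nonresponder/unassigned), `pfs_months`, `os_months`,
#' `pfs_event`, `os_event`. Optional: `subtype`, `mgmt`. Validates value
#' domains and that PFS does not exceed OS when both are observed.
#'
#' @param path file to read.
#' @return A data.frame, one row per sample.
#' @export
readSampleMetadata <- function(path) {
    df <- read.delim(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    need <- c("sample_id", "treatment", "response", "pfs_months",
              "os_months", "pfs_event", "os_event")
    miss <- setdiff(need, colnames(df))
    if (length(miss) > 0L)
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id: '",
             df$sample_id[duplicated(df$sample_id)][1L], "'")
    if (!all(df$treatment %in% .TREATMENTS))
        stop("treatment must be one of: ", paste(.TREATMENTS, collapse = ", "))
    if (!all(df$response %in% .RESPONSES))
        stop("response must be one of: ", paste(.RESPONSES, collapse = ", "))
    if (!all(df$pfs_event %in% c(0, 1)) || !all(df$os_event %in% c(0, 1)))
        stop("event flags must be 0 or 1")
    both <- !is.na(df$pfs_months) & !is.na(df$os_months)
    if (any(df$pfs_months[both] > df$os_months[both] + 1e-9))
        stop("pfs_months exceeds os_months for sample '",
             df$sample_id[both][which(df$pfs_months[both] >
                                      df$os_months[both] + 1e-9)[1L]], "'")
    df
}

#' Write sample metadata TSV
#'
#' @param metadata data.frame as returned by [simulateCohort()] /
#'   [readSampleMetadata()].
#' @param path output file.
#' @export
writeSampleMetadata <- function(metadata, path) {
    write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Write five-state aberration calls as BED5
#'
#' One line per maximal run of clones with identical status per sample and
#' chromosome, 0-based half-open, columns `chrom start end status sample`,
#' sorted lexicographically by chromosome then start (then sample). Runs are
#' bounded by clone coordinates: start of the first clone to end of the
#' last.
#'
#' @param x an [AcghExperiment-class] with a `calls` assay.
#' @param path output file.
#' @param includeNeutral write neutral runs too (default drops them).
#' @return The path, invisibly.
#' @export
writeSegmentsBED <- function(x, path, includeNeutral = FALSE) {
    calls <- aberrationCalls(x)
    cm <- cloneMap(x)
    chrom <- as.character(seqnames(cm))
    out <- list()
    for (s in colnames(calls)) {
        cs <- calls[, s]
        for (ch in unique(chrom)) {
            idx <- which(chrom == ch)
            v <- cs[idx]
            v[is.na(v)] <- "missing"
            r <- rle(v)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            keep <- r$values != "missing"
            if (!includeNeutral) keep <- keep & r$values != "neutral"
            if (!any(keep)) next
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch,
                start = start(cm)[idx[starts[keep]]] - 1L,
                end = end(cm)[idx[ends[keep]]],
                status = r$values[keep],
                sample = s,
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L) {
        bed <- data.frame(chrom = character(), start = integer(),
                          end = integer(), status = character(),
                          sample = character())
    } else {
        bed <- do.call(rbind, out)
        bed <- bed[order(bed$chrom, bed$start, bed$sample), , drop = FALSE]
    }
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
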