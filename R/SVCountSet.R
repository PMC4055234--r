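#' Construct an SVCountSet from ref/alt allele counts
#'
#' @param ref,alt numeric vectors of non-negative reference / alternative
#'   allele counts, one entry per individual. Non-integer "effective" counts
#'   are allowed.
#' @param ploidy integer vector (recycled) of per-individual ploidies, 1 or
#'   2. Default 2 (all diploid).
#' @param sampleIds character vector of unique sample identifiers; defaults
#'   to the names of \code{ref} or \code{S1, S2, ...}.
#'
#' @return an \linkS4class{SVCountSet}.
#'
#' @examples
#' cs <- SVCountSet(ref = c(5, 2, 0), alt = c(0, 2, 4),
#'                  sampleIds = c("NA12878", "HG00096", "HG00097"))
#' refCounts(cs)
#' totalCounts(cs)
#'
#' @export
SVCountSet <- function(ref, alt, ploidy = 2L, sampleIds = NULL) {
    if (length(ref) != length(alt))
        stop("'ref' and 'alt' must have the same length")
    n <- length(ref)
    ploidy <- as.integer(rep_len(ploidy, n))
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(names(ref))) names(ref)
                     else sprintf("S%d", seq_len(n))
    m <- matrix(NA_real_, nrow = 2L, ncol = n,
                dimnames = list(c("ref", "alt"), as.character(sampleIds)))
    if (n) {
        m["ref", ] <- as.numeric(ref)
        m["alt", ] <- as.numeric(alt)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(ploidy = ploidy,
                                       row.names = colnames(m)))
    new("SVCountSet", se)
}

#' @rdname SVCountSet
#' @param x an \code{SVCountSet}.
#' @export
setMethod("refCounts", "SVCountSet", function(x)
    SummarizedExperiment::assay(x, "counts")["ref", ])

#' @rdname SVCountSet
#' @export
setMethod("altCounts", "SVCountSet", function(x)
    SummarizedExperiment::assay(x, "counts")["alt", ])

#' @rdname SVCountSet
#' @export
setMethod("totalCounts", "SVCountSet", function(x)
    refCounts(x) + altCounts(x))

#' @rdname SVCountSet
#' @export
setMethod("ploidy", "SVCountSet", function(x)
    SummarizedExperiment::colData(x)$ploidy)

setMethod("show", "SVCountSet", function(object) {
    n <- ncol(object)
    nh <- sum(ploidy(object) == 1L)
    cat("SVCountSet with", n, "individuals",
        sprintf("(%d diploid, %d hemizygous)\n", n - nh, nh))
    k <- totalCounts(object)
    cat(sprintf("  total counts: %.6g (mean coverage %.3g)\n",
                sum(k), if (n) mean(k) else NA_real_))
    if (n) {
        show <- utils::head(colnames(object), 4L)
        cat("  samples:", paste(show, collapse = ", "),
            if (n > 4L) "..." else "", "\n")
    }
})

#' Read a 3/4-column allele-count table
#'
#' Reads the whitespace- or tab-delimited text format consumed by the
#' estimation functions: one row per individual with a sample identifier,
#' the number of reference-allele observations and the number of
#' alternative-allele observations, plus an optional fourth column with the
#' ploidy (1 or 2; 2 when absent). Counts may be non-integer effective
#' counts. Blank lines and lines starting with \code{#} are ignored.
#'
#' @param source a file path or a connection.
#' @return an \linkS4class{SVCountSet}.
#' @seealso \code{\link{writeCountTable}}
#' @examples
#' tf <- tempfile()
#' writeLines(c("# my variant", "NA12878 5 3", "HG00096 2.5 0.5 1"), tf)
#' readCountTable(tf)
#' @export
readCountTable <- function(source) {
    lines <- readLines(source)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    fields <- strsplit(trimws(lines[keep]), "[ \t]+")
    nf <- lengths(fields)
    bad <- nf < 3L | nf > 4L
    if (any(bad))
        stop("malformed count line ", keep[which(bad)[1L]],
             ": expected 3 or 4 fields, found ", nf[which(bad)[1L]])
    ids <- vapply(fields, `[`, character(1L), 1L)
    num <- function(i, what) {
        v <- suppressWarnings(as.numeric(
            vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                   character(1L))))
        bad <- is.na(v) & nf >= i
        if (any(bad))
            stop("line ", keep[which(bad)[1L]], ": non-numeric ", what)
        v
    }
    ref <- num(2L, "reference count")
    alt <- num(3L, "alternative count")
    pl <- num(4L, "ploidy")
    pl[is.na(pl)] <- 2
    if (any(ref < 0) || any(alt < 0)) {
        i <- which(ref < 0 | alt < 0)[1L]
        stop("line ", keep[i], ": negative count for sample '", ids[i], "'")
    }
    if (!all(pl %in% c(1, 2))) {
        i <- which(!pl %in% c(1, 2))[1L]
        stop("line ", keep[i], ": ploidy must be 1 or 2, found ", pl[i])
    }
    if (anyDuplicated(ids))
        stop("duplicate sample identifier: '", ids[anyDuplicated(ids)], "'")
    SVCountSet(ref = ref, alt = alt, ploidy = as.integer(pl),
               sampleIds = ids)
}

#' Write an SVCountSet as a 3/4-column count table
#'
#' Writes the tab-delimited format read by \code{\link{readCountTable}}.
#' The ploidy column is emitted only when some individual is not diploid,
#' keeping the common all-diploid case in the minimal 3-column shape.
#' Counts are formatted with 12 significant digits, so a write/read round
#' trip reproduces the table.
#'
#' @param x an \linkS4class{SVCountSet}.
#' @param sink a file path or a connection.
#' @return invisibly, \code{sink}.
#' @export
writeCountTable <- function(x, sink) {
    stopifnot(is(x, "SVCountSet"))
    fmt <- function(v) formatC(v, digits = 12, format = "g")
    cols <- list(colnames(x), fmt(refCounts(x)), fmt(altCounts(x)))
    if (any(ploidy(x) != 2L))
        cols <- c(cols, list(as.character(ploidy(x))))
    lines <- do.call(paste, c(cols, sep = "\t"))
    writeLines(lines, sink)
    invisible(sink)
}
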