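#' @import methods
#' @importFrom stats setNames
NULL

#' SVCountSet: per-individual allele counts for one structural variant
#'
#' An \code{SVCountSet} holds, for a single bi-allelic variant, the number of
#' times the reference and the alternative allele have been observed in each
#' individual, together with the individual's ploidy (2 for autosomes, 1 for
#' hemizygous samples such as male sex chromosomes). It extends
#' \linkS4class{SummarizedExperiment}: the single assay \code{"counts"} is a
#' 2 x N matrix with rows \code{"ref"} and \code{"alt"}, and the column data
#' carry the \code{ploidy}. Counts may be non-integer "effective" counts,
#' i.e. expected numbers of true observations after per-observation quality
#' weighting.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#'
#' @seealso \code{\link{SVCountSet}} (constructor),
#'   \code{\link{readCountTable}}, \code{\link{svFit}}
#' @name SVCountSet-class
#' @aliases SVCountSet-class
#' @exportClass SVCountSet
setClass("SVCountSet", contains = "SummarizedExperiment")

.validSVCountSet <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (nrow(m) != 2L || !identical(rownames(m), c("ref", "alt")))
            msg <- c(msg, "'counts' must have exactly two rows, 'ref' and 'alt'")
        if (any(!is.finite(m)) || any(m < 0))
            msg <- c(msg, "counts must be finite and non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!("ploidy" %in% colnames(cd)))
        msg <- c(msg, "colData must contain a 'ploidy' column")
    else if (!all(cd$ploidy %in% c(1L, 2L)))
        msg <- c(msg, "ploidy must be 1 or 2")
    ids <- colnames(object)
    if ((ncol(object) > 0L && is.null(ids)) || anyDuplicated(ids) ||
        any(!nzchar(ids)))
        msg <- c(msg, "sample identifiers must be present, non-empty and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("SVCountSet", .validSVCountSet)

#' SVFit: a converged EM fit of allele or genotype frequencies
#'
#' Result of \code{\link{svFit}}. Holds the maximum-likelihood frequency
#' estimates (allele frequency \code{psi} under Hardy-Weinberg equilibrium,
#' or free genotype frequencies \code{psiG} for diploids and \code{phiG} for
#' hemizygous individuals), the final count error rates, the observed-data
#' log-likelihood and its per-iteration trace, per-sample genotype
#' log-likelihoods and posterior probabilities, and convergence diagnostics.
#'
#' Genotypes are indexed by their number of reference alleles
#' \code{g in 0..m}: for diploids \code{g = 0} is the homozygous alternative,
#' \code{g = 1} the heterozygote, \code{g = 2} the homozygous reference; for
#' hemizygous samples \code{g = 0} carries the alternative and \code{g = 1}
#' the reference allele, and the \code{g = 2} column is structurally
#' impossible (log-likelihood \code{-Inf}, posterior 0).
#'
#' @slot mode "HWE" or "free".
#' @slot psi alternative-allele frequency estimate (HWE mode; \code{NA}
#'   otherwise).
#' @slot psiG diploid genotype frequency estimates over g = 0, 1, 2 (free
#'   mode; \code{NA} otherwise).
#' @slot phiG hemizygous genotype frequency estimates over g = 0, 1 (free
#'   mode with hemizygous samples; \code{NA} otherwise).
#' @slot epsRef,epsAlt final frequencies of erroneous counts among
#'   reference-labeled / alternative-labeled observations.
#' @slot lambda allele sampling bias used (odds of sampling the reference
#'   allele from a diploid heterozygote).
#' @slot logLik observed-data log-likelihood at the estimates.
#' @slot logLikTrace log-likelihood after each EM iteration.
#' @slot nIter number of EM iterations performed.
#' @slot converged logical; tolerance met before the iteration cap.
#' @slot haltedEps logical; an error-rate update reached 0.5, estimation was
#'   halted and the last valid estimates are reported (treat with caution).
#' @slot logLiks N x 3 matrix of per-sample genotype log-likelihoods.
#' @slot posteriors N x 3 matrix of per-sample genotype posterior
#'   probabilities.
#' @slot ploidy integer vector of per-sample ploidies.
#' @slot sampleIds character vector of sample identifiers.
#' @slot estimatedErrors logical; were the error rates co-estimated.
#'
#' @name SVFit-class
#' @aliases SVFit-class
#' @exportClass SVFit
setClass("SVFit",
    representation(
        mode = "character",
        psi = "numeric",
        psiG = "numeric",
        phiG = "numeric",
        epsRef = "numeric",
        epsAlt = "numeric",
        lambda = "numeric",
        logLik = "numeric",
        logLikTrace = "numeric",
        nIter = "integer",
        converged = "logical",
        haltedEps = "logical",
        logLiks = "matrix",
        posteriors = "matrix",
        ploidy = "integer",
        sampleIds = "character",
        estimatedErrors = "logical"
    )
)

setValidity("SVFit", function(object) {
    msg <- NULL
    if (!object@mode %in% c("HWE", "free"))
        msg <- c(msg, "mode must be 'HWE' or 'free'")
    if (object@mode == "HWE" &&
        (length(object@psi) != 1L || is.na(object@psi) ||
         object@psi < 0 || object@psi > 1))
        msg <- c(msg, "psi must be a single value in [0, 1] in HWE mode")
    n <- length(object@sampleIds)
    if (nrow(object@logLiks) != n || nrow(object@posteriors) != n)
        msg <- c(msg, "per-sample matrices must have one row per sample")
    if (is.null(msg)) TRUE else msg
})

#' SVTestResult: a likelihood-ratio test result
#'
#' Result of \code{\link{hweTest}} or
#' \code{\link{populationDifferenceTest}}. The statistic is
#' \code{2 * (logLikAlt - logLikNull)}, clamped at zero, and the p-value is
#' the upper tail of the chi-square distribution with \code{df} degrees of
#' freedom.
#'
#' @slot statistic likelihood-ratio statistic.
#' @slot df degrees of freedom.
#' @slot pValue upper-tail chi-square probability.
#' @slot logLikNull,logLikAlt log-likelihoods of the null and alternative
#'   models (for the population test, \code{logLikAlt} is the sum of the two
#'   separate fits).
#' @slot fits list of the underlying \linkS4class{SVFit} objects.
#' @slot test short label ("HWE" or "population-difference").
#'
#' @name SVTestResult-class
#' @aliases SVTestResult-class
#' @exportClass SVTestResult
setClass("SVTestResult",
    representation(
        statistic = "numeric",
        df = "integer",
        pValue = "numeric",
        logLikNull = "numeric",
        logLikAlt = "numeric",
        fits = "list",
        test = "character"
    )
)

setValidity("SVTestResult", function(object) {
    msg <- NULL
    if (object@statistic < 0)
        msg <- c(msg, "statistic must be non-negative")
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})
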