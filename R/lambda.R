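# Helpers to choose the allele-sampling-bias parameter before fitting.
# lambda is the odds of observing the reference allele in one draw from a
# diploid heterozygote; it must be supplied to svFit(), not estimated by it.

#' Rough allele-sampling-bias from variant type and size
#'
#' First approximation to the sampling bias \code{lambda} from empirical
#' log-log regressions of bias against variant length (natural-log
#' convention), calibrated on single-end 100 bp read mapping of known
#' deletion and insertion alleles:
#' \code{log(lambda) = -4.22 + 0.94 log(size)} for deletions (the known
#' deleted sequence is evidence of the longer, reference allele, so longer
#' deletions push the bias up) and
#' \code{log(lambda) = 3.84 - 0.87 log(size)} for insertions (the mirror
#' situation). For inversions \code{lambda = 1} is a fair default in the
#' absence of additional information.
#'
#' These are rough priors only (the regressions explain under half of the
#' variance, and local repeats or a different read layout change the
#' picture); values within a factor of two of the truth cause only minor
#' frequency biases, so the approximation is usually serviceable.
#'
#' @param type "deletion", "insertion" or "inversion".
#' @param size variant length in base pairs (>= 1); ignored for inversions.
#' @return the lambda estimate, with attribute \code{approximate = TRUE} as
#'   a reminder of its rough provenance.
#' @examples
#' lambdaFromSize("deletion", 1000)
#' lambdaFromSize("inversion")
#' @export
lambdaFromSize <- function(type = c("deletion", "insertion", "inversion"),
                           size = NULL) {
    type <- match.arg(type)
    if (type != "inversion") {
        stopifnot(length(size) == 1L, is.finite(size), size >= 1)
        val <- switch(type,
            deletion  = exp(-4.22 + 0.94 * log(size)),
            insertion = exp(3.84 - 0.87 * log(size)))
    } else {
        val <- 1
    }
    structure(val, approximate = TRUE)
}

#' Allele-sampling-bias from known heterozygotes
#'
#' If a subset of individuals is known to be heterozygous by external
#' evidence (PCR, high-coverage sequencing), the ratio of their pooled
#' reference to pooled alternative counts estimates \code{lambda} directly,
#' since every draw from a heterozygote reports the reference allele with
#' odds \code{lambda}.
#'
#' @param x an \linkS4class{SVCountSet} restricted to known heterozygotes.
#' @return the pooled-ratio estimate of lambda.
#' @examples
#' hets <- SVCountSet(ref = c(80, 70), alt = c(30, 20))
#' lambdaFromKnownHets(hets)  # 150 / 50 = 3
#' @export
lambdaFromKnownHets <- function(x) {
    stopifnot(is(x, "SVCountSet"))
    if (ncol(x) == 0L)
        stop("no individuals supplied")
    refTot <- sum(refCounts(x))
    altTot <- sum(altCounts(x))
    if (altTot == 0)
        stop("pooled alternative count is zero: the implied bias is ",
             "infinite; substitute a large finite lambda (e.g. 1e6), ",
             "which behaves equivalently at low coverage")
    refTot / altTot
}
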