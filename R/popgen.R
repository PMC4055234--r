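# --- posteriors and genotype calls ------------------------------------------

#' @describeIn SVFit-accessors posterior genotype probabilities. For an
#'   \code{SVFit} the stored matrix is returned; for a matrix of genotype
#'   log-likelihoods (as produced by \code{\link{genotypeLogLik}}) the
#'   posteriors are computed under the supplied frequency model:
#'   \code{P(g | data) = L(g) P(g | psi) / sum_g' L(g') P(g' | psi)} with the
#'   Hardy-Weinberg prior, or with the free genotype frequencies
#'   \code{psiG}/\code{phiG} in place of the prior.
#' @param ploidy integer vector of ploidies (matrix method).
#' @param psi,psiG,phiG frequency model for the matrix method: either an
#'   alternative-allele frequency \code{psi} (HWE) or genotype frequencies
#'   \code{psiG} (and \code{phiG} if hemizygotes are present).
#' @export
setMethod("genotypePosteriors", "matrix",
    function(object, ploidy = 2L, psi = NULL, psiG = NULL, phiG = NULL) {
        stopifnot(ncol(object) == 3L)
        n <- nrow(object)
        ploidy <- as.integer(rep_len(ploidy, n))
        model <- .asModel(psi, psiG, phiG)
        prior <- .priorMatrix(model, ploidy)
        ids <- if (!is.null(rownames(object))) rownames(object)
               else as.character(seq_len(n))
        lmax <- pmax(object[, 1L], object[, 2L], object[, 3L])
        w <- prior * exp(object - lmax)
        w[prior == 0] <- 0
        tot <- rowSums(w)
        if (any(!is.finite(tot) | tot == 0)) {
            i <- which(!is.finite(tot) | tot == 0)[1L]
            stop("sample '", ids[i], "' has zero posterior mass")
        }
        out <- w / tot
        dimnames(out) <- list(rownames(object), c("g0", "g1", "g2"))
        out
    })

#' @describeIn SVFit-accessors stored posterior matrix of a fit.
#' @export
setMethod("genotypePosteriors", "SVFit", function(object) object@posteriors)

#' Most probable genotype from posterior probabilities
#'
#' Returns the genotype (number of reference alleles) with the highest
#' posterior probability for each individual. Ties (within a relative
#' tolerance of 1e-9) are broken toward the heterozygote, then toward the
#' lower genotype, which minimizes the expected allele-count error and makes
#' calls deterministic.
#'
#' @param posterior a posterior probability matrix (columns g0, g1, g2) or a
#'   single posterior vector.
#' @param ploidy integer vector of ploidies (recycled). For hemizygous
#'   individuals only g = 0 and g = 1 exist and ties go to g = 0.
#' @return an integer vector of genotype indices.
#' @examples
#' mostProbableGenotype(c(0.5, 0.5, 0))   # tie -> heterozygote
#' @export
mostProbableGenotype <- function(posterior, ploidy = 2L) {
    if (is.null(dim(posterior)))
        posterior <- matrix(posterior, nrow = 1L)
    stopifnot(ncol(posterior) == 3L || ncol(posterior) == 2L)
    if (ncol(posterior) == 2L)
        posterior <- cbind(posterior, 0)
    n <- nrow(posterior)
    ploidy <- as.integer(rep_len(ploidy, n))
    out <- integer(n)
    for (i in seq_len(n)) {
        p <- posterior[i, ]
        pref <- if (ploidy[i] == 2L) c(2L, 1L, 3L) else c(1L, 2L)  # g=1,0,2 / g=0,1
        p <- p[pref]
        top <- max(p)
        j <- which(p >= top - 1e-9 * max(top, 1e-300))[1L]
        out[i] <- pref[j] - 1L
    }
    out
}

#' @describeIn SVFit-accessors most probable genotype per sample (ties to
#'   the heterozygote, then the lower genotype).
#' @export
setMethod("mostProbableGenotypes", "SVFit", function(object)
    setNames(mostProbableGenotype(object@posteriors, object@ploidy),
             object@sampleIds))

# --- scalar population statistics -------------------------------------------

#' Heterozygosity of a free-mode fit
#'
#' The maximum-likelihood frequency of the heterozygous diploid genotype,
#' estimated without assuming Hardy-Weinberg equilibrium, is a direct
#' estimate of heterozygosity. A fit made under the equilibrium assumption
#' has no free heterozygote frequency (its implied value is
#' \code{2 psi (1 - psi)}) and is rejected.
#'
#' @param object an \linkS4class{SVFit} with \code{mode == "free"}.
#' @return the estimated heterozygote frequency.
#' @export
setMethod("heterozygosity", "SVFit", function(object) {
    if (object@mode != "free")
        stop("heterozygosity needs a free-mode fit; under HWE it is ",
             "implied as 2*psi*(1-psi)")
    unname(object@psiG[2L])
})

#' Inbreeding coefficient from heterozygote and allele frequencies
#'
#' \code{F = 1 - psi1 / (2 psi (1 - psi))}: the relative deficit of
#' heterozygotes compared with the Hardy-Weinberg expectation, where
#' \code{psi1} is the (freely estimated) heterozygote frequency and
#' \code{psi} the alternative-allele frequency.
#'
#' @param psi1 heterozygote frequency in [0, 1].
#' @param psi alternative-allele frequency, strictly inside (0, 1).
#' @return the inbreeding coefficient (1 at complete inbreeding, 0 under
#'   HWE; negative values indicate heterozygote excess).
#' @examples
#' inbreedingCoefficient(0.5, 0.5)  # 0: HWE proportions
#' inbreedingCoefficient(0, 0.5)    # 1: no heterozygotes at all
#' @export
inbreedingCoefficient <- function(psi1, psi) {
    stopifnot(length(psi1) == 1L, length(psi) == 1L,
              psi1 >= 0, psi1 <= 1)
    if (!(psi > 0 && psi < 1))
        stop("the inbreeding coefficient is undefined at psi = 0 or 1")
    1 - psi1 / (2 * psi * (1 - psi))
}

#' Hudson's two-population F_ST estimator
#'
#' Single-locus fixation index between two populations from their
#' alternative-allele frequencies and the numbers of chromosomes sampled:
#' \deqn{\hat F_{ST} = \frac{(p_1 - p_2)^2 - p_1(1-p_1)/(n_1-1)
#'   - p_2(1-p_2)/(n_2-1)}{p_1(1-p_2) + p_2(1-p_1)}}
#' The numerator corrects the squared frequency difference for sampling
#' noise; the denominator is the between-population heterozygosity.
#'
#' @param p1,p2 allele frequencies in [0, 1].
#' @param n1,n2 numbers of chromosomes sampled (>= 2); twice the number of
#'   diploid individuals plus the number of hemizygous ones.
#' @return the F_ST estimate (can be slightly negative by sampling noise).
#' @examples
#' hudsonFst(0.2, 100, 0.4, 100)
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
    stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 2, n2 >= 2)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (den == 0)
        stop("F_ST is undefined: no between-population heterozygosity ",
             "(both populations fixed)")
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    num / den
}

# --- likelihood-ratio tests -------------------------------------------------

.makeTest <- function(l1, l0, df, fits, label) {
    stat <- max(0, 2 * (l1 - l0))
    new("SVTestResult",
        statistic = stat, df = as.integer(df),
        pValue = stats::pchisq(stat, df = df, lower.tail = FALSE),
        logLikNull = l0, logLikAlt = l1, fits = fits, test = label)
}

#' Likelihood-ratio test for Hardy-Weinberg equilibrium
#'
#' Fits the allele counts twice — under the equilibrium assumption (one
#' allele frequency) and with free genotype frequencies — and compares the
#' log-likelihoods. Twice their difference follows a chi-square distribution
#' with 1 degree of freedom when all individuals are diploid, or 2 when
#' hemizygous genotype frequencies are estimated as well. The sampling bias
#' and the error rates are shared between the two fits.
#'
#' @param x an \linkS4class{SVCountSet}.
#' @param ... parameters passed to \code{\link{svFit}} (e.g. \code{lambda},
#'   \code{epsRef}, \code{epsAlt}, \code{estimateErrors}).
#' @return an \linkS4class{SVTestResult}; the fits are available in its
#'   \code{fits} slot as \code{null} (HWE) and \code{alt} (free).
#' @examples
#' sim <- simulateCounts(n = 100, psi = 0.4, meanCoverage = 4, seed = 7)
#' hweTest(sim$counts)
#' @export
hweTest <- function(x, ...) {
    f0 <- svFit(x, mode = "HWE", ...)
    f1 <- svFit(x, mode = "free", ...)
    df <- if (any(ploidy(x) == 1L)) 2L else 1L
    .makeTest(f1@logLik, f0@logLik, df,
              list(null = f0, alt = f1), "HWE")
}

#' Likelihood-ratio test for an allele-frequency difference
#'
#' Tests whether two samples share one allele frequency. Three fits are run
#' under Hardy-Weinberg equilibrium: one per sample (log-likelihoods
#' \code{l_a}, \code{l_b}) and one on the pooled counts (\code{l_0}). The
#' models are nested, so \code{2 (l_a + l_b - l_0)} follows a chi-square
#' distribution with 1 degree of freedom under the null. The sampling bias
#' and the error rates are held fixed and shared across the three fits;
#' co-estimating errors per population would change the degrees of freedom
#' and is not offered.
#'
#' @param xa,xb two \linkS4class{SVCountSet}s (disjoint sample identifiers
#'   are not required; pooling concatenates the records).
#' @param ... parameters passed to \code{\link{svFit}};
#'   \code{estimateErrors} is not allowed here.
#' @return an \linkS4class{SVTestResult} with fits \code{a}, \code{b} and
#'   \code{joint}.
#' @export
populationDifferenceTest <- function(xa, xb, ...) {
    args <- list(...)
    if (isTRUE(args$estimateErrors))
        stop("error rates must be fixed and shared across the three fits; ",
             "per-population co-estimation would change the degrees of freedom")
    fa <- svFit(xa, mode = "HWE", ...)
    fb <- svFit(xb, mode = "HWE", ...)
    pooled <- SVCountSet(
        ref = c(unname(refCounts(xa)), unname(refCounts(xb))),
        alt = c(unname(altCounts(xa)), unname(altCounts(xb))),
        ploidy = c(ploidy(xa), ploidy(xb)),
        sampleIds = make.unique(c(colnames(xa), colnames(xb))))
    f0 <- svFit(pooled, mode = "HWE", ...)
    .makeTest(fa@logLik + fb@logLik, f0@logLik, 1L,
              list(a = fa, b = fb, joint = f0), "population-difference")
}
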