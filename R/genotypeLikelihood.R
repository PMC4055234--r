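# x * log(y) with the empty-product convention 0 * log(0) = 0;
# a zero base with a positive exponent still yields -Inf.
.xlogy <- function(x, y) {
    out <- x * log(y)
    out[x == 0] <- 0
    out
}

.checkErrBias <- function(lambda, epsRef, epsAlt) {
    stopifnot(length(lambda) == 1L, is.finite(lambda), lambda > 0,
              length(epsRef) == 1L, epsRef >= 0, epsRef < 0.5,
              length(epsAlt) == 1L, epsAlt >= 0, epsAlt < 0.5)
}

#' Genotype log-likelihoods from allele counts
#'
#' Computes, for each individual, the log-likelihood of every genotype given
#' its reference and alternative allele counts. Genotypes are indexed by the
#' number of reference alleles \code{g}. Writing \code{l} for the reference
#' count and \code{k} for the total count, the diploid likelihoods are
#' \deqn{L(0) = \epsilon_r^{l} (1-\epsilon_a)^{k-l}}
#' \deqn{L(1) = (1+\lambda)^{-k} (\epsilon_r + \lambda(1-\epsilon_r))^{l}
#'              ((1-\epsilon_a) + \lambda\epsilon_a)^{k-l}}
#' \deqn{L(2) = (1-\epsilon_r)^{l} \epsilon_a^{k-l}}
#' where \eqn{\lambda} is the allele sampling bias (the odds of sampling the
#' reference allele from a heterozygote) and \eqn{\epsilon_r},
#' \eqn{\epsilon_a} are the frequencies of erroneous counts among
#' reference-labeled and alternative-labeled observations. Hemizygous
#' individuals (ploidy 1) have the likelihoods of the corresponding
#' homozygotes: \code{L(0)} as above and \code{L(1) = L(2)} of the diploid
#' case; their \code{g = 2} column is \code{-Inf}.
#'
#' Everything is evaluated in log space with the convention
#' \eqn{0^0 = 1} (zero counts contribute nothing), so an individual with no
#' counts has log-likelihood 0 for every genotype.
#'
#' @param ref,alt numeric vectors of reference / alternative counts (or an
#'   \linkS4class{SVCountSet} as \code{ref}, in which case \code{alt} and
#'   \code{ploidy} are taken from it).
#' @param ploidy integer vector, 1 or 2 (recycled).
#' @param lambda allele sampling bias, a single positive finite number;
#'   1 means unbiased. Truly infinite bias must be approximated by a large
#'   finite value (e.g. 1e6); a wide range of large values behaves
#'   identically at low coverage.
#' @param epsRef,epsAlt error-count frequencies, each in [0, 0.5).
#'
#' @return an N x 3 matrix of log-likelihoods with columns \code{g0},
#'   \code{g1}, \code{g2}.
#'
#' @examples
#' genotypeLogLik(ref = 2, alt = 2, lambda = 1)   # (-Inf, log 1/16, -Inf)
#' genotypeLogLik(ref = 1, alt = 0, lambda = 3)   # het term log(3/4)
#'
#' @export
genotypeLogLik <- function(ref, alt = NULL, ploidy = 2L, lambda = 1,
                           epsRef = 0, epsAlt = 0) {
    if (is(ref, "SVCountSet")) {
        x <- ref
        ref <- refCounts(x); alt <- altCounts(x); ploidy <- ploidy(x)
    }
    stopifnot(length(ref) == length(alt), all(ref >= 0), all(alt >= 0))
    .checkErrBias(lambda, epsRef, epsAlt)
    n <- length(ref)
    ploidy <- as.integer(rep_len(ploidy, n))
    stopifnot(all(ploidy %in% c(1L, 2L)))
    l <- as.numeric(ref)
    a <- as.numeric(alt)
    k <- l + a
    ll0 <- .xlogy(l, epsRef) + .xlogy(a, 1 - epsAlt)
    llRef <- .xlogy(l, 1 - epsRef) + .xlogy(a, epsAlt)
    llHet <- -k * log1p(lambda) +
        .xlogy(l, epsRef + lambda * (1 - epsRef)) +
        .xlogy(a, (1 - epsAlt) + lambda * epsAlt)
    out <- cbind(g0 = ll0, g1 = llHet, g2 = llRef)
    hemi <- ploidy == 1L
    if (any(hemi)) {
        out[hemi, "g1"] <- llRef[hemi]
        out[hemi, "g2"] <- -Inf
    }
    rownames(out) <- if (!is.null(names(l))) names(l) else NULL
    out
}

# Genotype prior matrix (N x 3) for a frequency model.
# HWE: diploids (psi^2, 2 psi (1-psi), (1-psi)^2); hemizygotes (psi, 1-psi, 0).
# free: diploids psiG; hemizygotes (phiG, 0). g counts reference alleles and
# psi is the alternative-allele frequency, hence psi^2 at g = 0.
.priorMatrix <- function(model, ploidy) {
    n <- length(ploidy)
    out <- matrix(0, n, 3L, dimnames = list(NULL, c("g0", "g1", "g2")))
    dip <- ploidy == 2L
    if (model$mode == "HWE") {
        p <- model$psi
        if (any(dip))
            out[dip, ] <- matrix(c(p^2, 2 * p * (1 - p), (1 - p)^2),
                                 sum(dip), 3L, byrow = TRUE)
        if (any(!dip))
            out[!dip, 1:2] <- matrix(c(p, 1 - p), sum(!dip), 2L, byrow = TRUE)
    } else {
        if (any(dip))
            out[dip, ] <- matrix(model$psiG, sum(dip), 3L, byrow = TRUE)
        if (any(!dip))
            out[!dip, 1:2] <- matrix(model$phiG, sum(!dip), 2L, byrow = TRUE)
    }
    out
}
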