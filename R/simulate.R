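# Synthetic count tables with known ground truth, mirroring the simulation
# design the estimators were validated on: Hardy-Weinberg genotypes at a
# chosen alternative-allele frequency, Poisson per-individual coverage,
# biased allele sampling from heterozygotes with odds lambda, and a small
# per-count label-flip error (0.005 by default).

#' Simulate an allele-count table with known genotypes
#'
#' For each individual, a genotype is drawn (binomially from the
#' alternative-allele frequency \code{psi} under Hardy-Weinberg equilibrium,
#' or from explicit genotype frequencies), a total count depth is drawn from
#' a Poisson distribution, and each count samples a true allele — the
#' reference with probability 1 for the all-reference genotype, 0 for the
#' all-alternative genotype, and \code{lambda / (1 + lambda)} for a diploid
#' heterozygote — whose label is then flipped with probability
#' \code{flipError}. Under this symmetric label-flip mechanism the genotype
#' likelihood model with \code{epsRef = epsAlt = flipError} is exactly the
#' per-count sampling law, so fits on simulated data probe the estimators
#' under a correctly specified model (up to the flip/conditional-frequency
#' distinction, negligible at rates this small).
#'
#' @param n number of individuals.
#' @param psi true alternative-allele frequency in [0, 1].
#' @param meanCoverage Poisson mean of the per-individual total count.
#' @param lambda true allele sampling bias in heterozygotes.
#' @param flipError per-count label-flip probability (< 0.5); the default
#'   0.005 matches the validation simulations.
#' @param ploidy per-individual ploidies (recycled), 1 or 2. Hemizygous
#'   individuals draw g = 0 (alternative) with probability \code{psi}.
#' @param genotypeFreqs optional list with \code{psiG} (length 3) and/or
#'   \code{phiG} (length 2) overriding the HWE genotype law.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#'
#' @return a list with \code{counts} (an \linkS4class{SVCountSet}),
#'   \code{genotypes} (integer vector of true genotypes, = number of
#'   reference alleles) and \code{truth} (a data.frame with sample_id,
#'   true_g and ploidy, ready to write as a TSV).
#'
#' @examples
#' sim <- simulateCounts(n = 5, psi = 0.3, meanCoverage = 4, seed = 42)
#' sim$truth
#'
#' @export
simulateCounts <- function(n, psi, meanCoverage, lambda = 1,
                           flipError = 0.005, ploidy = 2L,
                           genotypeFreqs = NULL, seed = NULL) {
    stopifnot(n >= 1, psi >= 0, psi <= 1, meanCoverage > 0,
              flipError >= 0, flipError < 0.5, lambda > 0)
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(rm(".Random.seed", envir = globalenv()))
        }
        set.seed(seed)
    }
    ploidy <- as.integer(rep_len(ploidy, n))
    stopifnot(all(ploidy %in% c(1L, 2L)))
    g <- integer(n)
    dip <- ploidy == 2L
    if (is.null(genotypeFreqs)) {
        # g counts reference alleles; each of the m copies is the
        # alternative with probability psi
        g[dip] <- stats::rbinom(sum(dip), 2L, 1 - psi)
        g[!dip] <- stats::rbinom(sum(!dip), 1L, 1 - psi)
    } else {
        psiG <- genotypeFreqs$psiG
        phiG <- genotypeFreqs$phiG
        if (any(dip)) {
            stopifnot(length(psiG) == 3L, abs(sum(psiG) - 1) < 1e-8)
            g[dip] <- sample(0:2, sum(dip), replace = TRUE, prob = psiG)
        }
        if (any(!dip)) {
            stopifnot(length(phiG) == 2L, abs(sum(phiG) - 1) < 1e-8)
            g[!dip] <- sample(0:1, sum(!dip), replace = TRUE, prob = phiG)
        }
    }
    k <- stats::rpois(n, meanCoverage)
    # probability that one draw carries a true reference allele
    pRef <- ifelse(g == ploidy, 1, ifelse(g == 0L, 0, lambda / (1 + lambda)))
    trueRef <- stats::rbinom(n, k, pRef)
    trueAlt <- k - trueRef
    # symmetric label flips
    refToAlt <- stats::rbinom(n, trueRef, flipError)
    altToRef <- stats::rbinom(n, trueAlt, flipError)
    l <- trueRef - refToAlt + altToRef
    ids <- sprintf("sim%0*d", nchar(n), seq_len(n))
    counts <- SVCountSet(ref = l, alt = k - l, ploidy = ploidy,
                         sampleIds = ids)
    list(counts = counts,
         genotypes = setNames(g, ids),
         truth = data.frame(sample_id = ids, true_g = g, ploidy = ploidy,
                            stringsAsFactors = FALSE))
}

#' Simulate two independent populations
#'
#' Draws two count tables from independent random streams, e.g. for
#' calibrating or powering the population-difference test. Each config is a
#' list of arguments for \code{\link{simulateCounts}} and must include a
#' \code{seed} so the streams are well defined.
#'
#' @param configA,configB argument lists for \code{\link{simulateCounts}}.
#' @return a list with elements \code{a} and \code{b}, each a
#'   \code{simulateCounts} result.
#' @examples
#' two <- simulateTwoPopulations(
#'   list(n = 50, psi = 0.2, meanCoverage = 4, seed = 1),
#'   list(n = 50, psi = 0.8, meanCoverage = 4, seed = 2))
#' @export
simulateTwoPopulations <- function(configA, configB) {
    stopifnot(!is.null(configA$seed), !is.null(configB$seed))
    list(a = do.call(simulateCounts, configA),
         b = do.call(simulateCounts, configB))
}
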