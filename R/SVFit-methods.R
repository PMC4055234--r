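#' Accessors for SVFit objects
#'
#' @param object an \linkS4class{SVFit}.
#' @param ... unused.
#' @name SVFit-accessors
NULL

#' @describeIn SVFit-accessors alternative-allele frequency estimate (HWE
#'   mode).
#' @export
setMethod("psiHat", "SVFit", function(object) {
    if (object@mode != "HWE")
        stop("psiHat is defined for HWE-mode fits; see genotypeFreqs()")
    object@psi
})

#' @describeIn SVFit-accessors genotype frequency estimates of a free-mode
#'   fit: a list with \code{psiG} (diploid, g = 0..2) and \code{phiG}
#'   (hemizygous, g = 0..1; NA when no hemizygous individuals were present).
#' @export
setMethod("genotypeFreqs", "SVFit", function(object) {
    if (object@mode != "free")
        stop("genotypeFreqs is defined for free-mode fits; see psiHat()")
    list(psiG = setNames(object@psiG, c("g0", "g1", "g2")),
         phiG = setNames(object@phiG, c("g0", "g1")))
})

#' @describeIn SVFit-accessors final error-rate estimates (or the fixed
#'   input values), named \code{epsRef} and \code{epsAlt}.
#' @export
setMethod("errorRates", "SVFit", function(object)
    c(epsRef = object@epsRef, epsAlt = object@epsAlt))

#' @describeIn SVFit-accessors per-sample genotype log-likelihood matrix.
#' @export
setMethod("genotypeLikelihoods", "SVFit", function(object) object@logLiks)

#' @describeIn SVFit-accessors observed-data log-likelihood at the
#'   estimates.
#' @export
setMethod("logLik", "SVFit", function(object, ...) {
    val <- object@logLik
    attr(val, "df") <- switch(object@mode,
        HWE = 1L,
        free = if (any(object@ploidy == 1L)) 3L else 2L)
    class(val) <- "logLik"
    val
})

setMethod("show", "SVFit", function(object) {
    cat("SVFit (", object@mode, " mode, ",
        length(object@sampleIds), " individuals)\n", sep = "")
    if (object@mode == "HWE") {
        cat(sprintf("  alternative-allele frequency psi = %.6g\n", object@psi))
    } else {
        cat(sprintf("  diploid genotype frequencies (g=0,1,2): %s\n",
                    paste(sprintf("%.6g", object@psiG), collapse = ", ")))
        if (!anyNA(object@phiG))
            cat(sprintf("  hemizygous genotype frequencies (g=0,1): %s\n",
                        paste(sprintf("%.6g", object@phiG), collapse = ", ")))
    }
    cat(sprintf("  lambda = %.6g; epsRef = %.3g, epsAlt = %.3g%s\n",
                object@lambda, object@epsRef, object@epsAlt,
                if (object@estimatedErrors) " (co-estimated)" else ""))
    cat(sprintf("  log-likelihood = %.6f after %d iterations (%s)\n",
                object@logLik, object@nIter,
                if (object@haltedEps) "HALTED: error rate reached 0.5"
                else if (object@converged) "converged" else "iteration cap"))
})

setMethod("show", "SVTestResult", function(object) {
    cat(object@test, "likelihood-ratio test\n")
    cat(sprintf("  2*(l1 - l0) = %.6g on %d df, p = %.4g\n",
                object@statistic, object@df, object@pValue))
    cat(sprintf("  logLik null = %.6f, alt = %.6f\n",
                object@logLikNull, object@logLikAlt))
})
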