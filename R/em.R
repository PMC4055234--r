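# --- E-step -----------------------------------------------------------------
# Posterior genotype probabilities and the expected sufficient statistics:
#   Dg, Hg  expected numbers of diploid / hemizygous individuals per genotype
#   R0, R2  expected reference-count mass in the all-alternative (g = 0) and
#           all-reference (g = m) classes (hemizygotes included)
#   A0, A2  the same for alternative-count mass
#   C1r,C1a expected reference / alternative count mass in diploid
#           heterozygotes (needed by the lambda != 1 error M-step)
.eStep <- function(ll, prior, l, a, ploidy, sampleIds) {
    lmax <- pmax(ll[, 1L], ll[, 2L], ll[, 3L])
    w <- prior * exp(ll - lmax)
    w[prior == 0] <- 0        # 0 * exp(-Inf - (-Inf)) guards
    tot <- rowSums(w)
    if (any(!is.finite(tot) | tot == 0)) {
        i <- which(!is.finite(tot) | tot == 0)[1L]
        stop("sample '", sampleIds[i],
             "' has zero posterior mass for every genotype; ",
             "its counts are impossible under the current parameters")
    }
    post <- w / tot
    dip <- ploidy == 2L
    pd <- post[dip, , drop = FALSE]
    ph <- post[!dip, , drop = FALSE]
    list(
        post = post,
        Dg = colSums(pd),
        Hg = colSums(ph[, 1:2, drop = FALSE]),
        D = sum(dip), H = sum(!dip), N = length(l),
        R0 = sum(pd[, 1L] * l[dip]) + sum(ph[, 1L] * l[!dip]),
        R2 = sum(pd[, 3L] * l[dip]) + sum(ph[, 2L] * l[!dip]),
        A0 = sum(pd[, 1L] * a[dip]) + sum(ph[, 1L] * a[!dip]),
        A2 = sum(pd[, 3L] * a[dip]) + sum(ph[, 2L] * a[!dip]),
        C1r = sum(pd[, 2L] * l[dip]),
        C1a = sum(pd[, 2L] * a[dip])
    )
}

# --- M-step: frequencies ----------------------------------------------------
# HWE:  psi' = (2 D0 + D1 + H0) / (2 (D0 + D1 + D2) + H0 + H1)
#       (numerator counts alternative alleles: g is the number of REFERENCE
#        alleles, so g = 0 diploids carry two alternative copies)
# free: psiG' = Dg / D, phiG' = Hg / H
.mStepFrequencies <- function(st, mode) {
    if (mode == "HWE") {
        num <- 2 * st$Dg[1L] + st$Dg[2L] + st$Hg[1L]
        den <- 2 * sum(st$Dg) + sum(st$Hg)
        if (den == 0) stop("no individuals: cannot update frequencies")
        list(mode = "HWE", psi = unname(num / den))
    } else {
        if (st$D == 0 && st$H == 0)
            stop("no individuals: cannot update frequencies")
        list(mode = "free",
             psiG = if (st$D > 0) unname(st$Dg / st$D) else rep(NA_real_, 3L),
             phiG = if (st$H > 0) unname(st$Hg / st$H) else rep(NA_real_, 2L))
    }
}

# --- M-step: error rates ----------------------------------------------------
# The eps-dependent part of the expected complete-data log-likelihood is, for
# the reference error rate (and symmetrically for the alternative one with
# mu = 1/lambda),
#   Q(x) = Z log x + C log(x + mu (1 - x)) + W log(1 - x)
# a concave function on (0, 1). Its stationary condition is the quadratic
#   -(1 - mu)(Z + C + W) x^2 + (Z (1 - 2 mu) + C (1 - mu) - mu W) x + mu Z = 0
# solved analytically below; when no stationary point exists in (0, 1) the
# maximizer sits at a boundary. Estimation halts when the maximizer reaches
# 0.5 (erroneous counts are assumed to be a minority).
.qFun <- function(x, Z, C, W, mu) {
    .xlogy(Z, x) + .xlogy(C, x + mu * (1 - x)) + .xlogy(W, 1 - x)
}

.maxQ <- function(Z, C, W, mu, fallback) {
    if (Z + C + W == 0) return(fallback)   # no count mass: keep current value
    if (Z == 0 && W == 0) return(fallback) # Q depends on x only through C term
    qa <- -(1 - mu) * (Z + C + W)
    qb <- Z * (1 - 2 * mu) + C * (1 - mu) - mu * W
    qc <- mu * Z
    cand <- numeric(0)
    if (abs(qa) > .Machine$double.eps * (Z + C + W)) {
        disc <- qb^2 - 4 * qa * qc
        if (disc >= 0) {
            sq <- sqrt(disc)
            cand <- c((-qb + sq) / (2 * qa), (-qb - sq) / (2 * qa))
        }
    } else if (qb != 0) {
        cand <- -qc / qb
    }
    cand <- cand[is.finite(cand) & cand > 0 & cand < 1]
    if (Z == 0) cand <- c(cand, 0)
    if (W == 0) cand <- c(cand, 1 - 1e-12)
    if (!length(cand)) return(fallback)
    cand[which.max(.qFun(cand, Z, C, W, mu))]
}

.mStepErrors <- function(st, lambda, current) {
    if (lambda == 1) {
        # at lambda = 1 the heterozygote term is constant in eps and the
        # maximizers have the closed forms R0/(R0+R2) and A2/(A0+A2)
        epsR <- if (st$R0 + st$R2 > 0) st$R0 / (st$R0 + st$R2) else current[1L]
        epsA <- if (st$A0 + st$A2 > 0) st$A2 / (st$A0 + st$A2) else current[2L]
    } else {
        epsR <- .maxQ(st$R0, st$C1r, st$R2, mu = lambda,     fallback = current[1L])
        epsA <- .maxQ(st$A2, st$C1a, st$A0, mu = 1 / lambda, fallback = current[2L])
    }
    c(epsRef = unname(epsR), epsAlt = unname(epsA))
}

# --- observed-data log-likelihood -------------------------------------------

#' Observed-data log-likelihood of a frequency model
#'
#' Sum over individuals of \code{log sum_g prior(g) L(g)}, the quantity the
#' EM algorithm maximizes. The prior is the Hardy-Weinberg expansion of the
#' alternative-allele frequency \code{psi}, or the free genotype frequencies
#' \code{psiG} (diploids) and \code{phiG} (hemizygotes).
#'
#' @param x an \linkS4class{SVCountSet}.
#' @param psi alternative-allele frequency in [0, 1] (HWE model), or
#'   \code{NULL} when \code{psiG} is given.
#' @param psiG,phiG free genotype frequencies over g = 0..2 (diploid) and
#'   g = 0..1 (hemizygous); each must sum to 1.
#' @param lambda,epsRef,epsAlt likelihood parameters, see
#'   \code{\link{genotypeLogLik}}.
#' @return a single number (log-likelihood).
#' @examples
#' cs <- SVCountSet(ref = c(1, 3), alt = c(1, 0))
#' observedLogLik(cs, psi = 0.5)
#' @export
observedLogLik <- function(x, psi = NULL, psiG = NULL, phiG = NULL,
                           lambda = 1, epsRef = 0, epsAlt = 0) {
    stopifnot(is(x, "SVCountSet"))
    model <- .asModel(psi, psiG, phiG)
    ll <- genotypeLogLik(x, lambda = lambda, epsRef = epsRef,
                         epsAlt = epsAlt)
    .obsLogLik(ll, .priorMatrix(model, ploidy(x)), colnames(x))
}

.obsLogLik <- function(ll, prior, sampleIds) {
    lmax <- pmax(ll[, 1L], ll[, 2L], ll[, 3L])
    lmax[!is.finite(lmax)] <- 0
    w <- prior * exp(ll - lmax)
    w[prior == 0] <- 0
    tot <- rowSums(w)
    if (any(!is.finite(tot) | tot == 0)) {
        i <- which(!is.finite(tot) | tot == 0)[1L]
        stop("sample '", sampleIds[i],
             "' has zero likelihood under every genotype")
    }
    sum(log(tot) + lmax)
}

.asModel <- function(psi, psiG, phiG) {
    if (!is.null(psi)) {
        stopifnot(is.null(psiG), length(psi) == 1L, psi >= 0, psi <= 1)
        list(mode = "HWE", psi = psi)
    } else {
        stopifnot(!is.null(psiG), length(psiG) == 3L, all(psiG >= 0),
                  abs(sum(psiG) - 1) < 1e-8)
        if (is.null(phiG)) phiG <- c(NA_real_, NA_real_)
        else stopifnot(length(phiG) == 2L, all(phiG >= 0),
                       abs(sum(phiG) - 1) < 1e-8)
        list(mode = "free", psiG = psiG, phiG = phiG)
    }
}

# --- the EM driver ----------------------------------------------------------

#' Fit allele or genotype frequencies by expectation-maximization
#'
#' Maximum-likelihood estimation of the alternative-allele frequency
#' \code{psi} under Hardy-Weinberg equilibrium (\code{mode = "HWE"}), or of
#' the genotype frequencies \code{psiG} (diploids) and \code{phiG}
#' (hemizygotes) without that assumption (\code{mode = "free"}), from
#' per-individual allele counts. Genotypes are treated as missing data: each
#' EM iteration computes posterior genotype probabilities given the current
#' frequencies (E-step) and re-estimates the frequencies — and optionally
#' the count error rates — from the expected genotype counts (M-step). The
#' observed-data log-likelihood never decreases along the iterations.
#'
#' The allele sampling bias \code{lambda} is always held fixed: estimating
#' it jointly would cost the accuracy of extreme frequency estimates, and it
#' can be obtained externally (see \code{\link{lambdaFromSize}} and
#' \code{\link{lambdaFromKnownHets}}). When \code{estimateErrors = TRUE} the
#' error rates are updated each iteration: in closed form when
#' \code{lambda == 1}, otherwise as the root of a quadratic stationary
#' condition. If an update reaches 0.5 (erroneous counts would no longer be
#' a minority) estimation halts, the last valid estimates are returned and
#' \code{haltedEps} is set. Error co-estimation is statistically demanding:
#' a warning is emitted when the mean coverage is below 4 or fewer than 100
#' individuals are available, where a-priori error rates are preferable.
#'
#' @param x an \linkS4class{SVCountSet}; at least one individual must have
#'   counts.
#' @param mode \code{"HWE"} or \code{"free"}.
#' @param lambda allele sampling bias (odds of sampling the reference allele
#'   from a diploid heterozygote); 1 means unbiased.
#' @param epsRef,epsAlt frequencies of erroneous counts among reference- /
#'   alternative-labeled observations, each in [0, 0.5). Used as fixed
#'   values, or as starting values when \code{estimateErrors = TRUE}.
#' @param estimateErrors logical; co-estimate the error rates.
#' @param tol convergence tolerance on the change of the observed-data
#'   log-likelihood.
#' @param maxIter iteration cap.
#' @param psiInit,psiGInit,phiGInit starting frequencies (interior defaults).
#'
#' @return an \linkS4class{SVFit}.
#'
#' @examples
#' sim <- simulateCounts(n = 200, psi = 0.3, meanCoverage = 4, seed = 1)
#' fit <- svFit(sim$counts)
#' psiHat(fit)
#'
#' @export
svFit <- function(x, mode = c("HWE", "free"), lambda = 1,
                  epsRef = 1e-5, epsAlt = 1e-5, estimateErrors = FALSE,
                  tol = 1e-8, maxIter = 10000L, psiInit = 0.5,
                  psiGInit = c(0.25, 0.5, 0.25), phiGInit = c(0.5, 0.5)) {
    stopifnot(is(x, "SVCountSet"), tol > 0, maxIter >= 1)
    mode <- match.arg(mode)
    .checkErrBias(lambda, epsRef, epsAlt)
    l <- unname(refCounts(x)); a <- unname(altCounts(x))
    m <- ploidy(x); ids <- colnames(x)
    n <- length(l)
    if (n == 0L || all(l + a == 0))
        stop("estimation needs at least one individual with counts")
    if (estimateErrors && (mean(l + a) < 4 || n < 100))
        warning("error-rate co-estimation with mean coverage < 4 or fewer ",
                "than 100 individuals is unreliable; a-priori estimates of ",
                "epsRef/epsAlt are recommended")

    model <- if (mode == "HWE") list(mode = "HWE", psi = psiInit)
             else list(mode = "free", psiG = psiGInit,
                       phiG = if (any(m == 1L)) phiGInit else c(NA_real_, NA_real_))
    eps <- c(epsRef, epsAlt)
    ll <- genotypeLogLik(l, a, m, lambda, eps[1L], eps[2L])
    trace <- numeric(0)
    prev <- NA_real_
    converged <- FALSE
    halted <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        st <- .eStep(ll, .priorMatrix(model, m), l, a, m, ids)
        model <- .mStepFrequencies(st, mode)
        if (estimateErrors) {
            e <- .mStepErrors(st, lambda, eps)
            if (any(e >= 0.5)) {   # erroneous counts no longer a minority
                halted <- TRUE
                it <- it - 1L      # the aborted update does not count
                break
            }
            if (any(e != eps)) {
                eps <- unname(e)
                ll <- genotypeLogLik(l, a, m, lambda, eps[1L], eps[2L])
            }
        }
        cur <- .obsLogLik(ll, .priorMatrix(model, m), ids)
        trace <- c(trace, cur)
        if (!is.na(prev) && abs(cur - prev) < tol) {
            converged <- TRUE
            break
        }
        prev <- cur
        # the boundary is absorbing under the updates: stop there
        if (mode == "HWE" && (model$psi == 0 || model$psi == 1)) {
            converged <- TRUE
            break
        }
    }
    post <- .eStep(ll, .priorMatrix(model, m), l, a, m, ids)$post
    rownames(post) <- ids
    rownames(ll) <- ids
    final <- if (length(trace)) trace[length(trace)]
             else .obsLogLik(ll, .priorMatrix(model, m), ids)
    new("SVFit",
        mode = model$mode,
        psi = if (mode == "HWE") model$psi else NA_real_,
        psiG = if (mode == "free") model$psiG else rep(NA_real_, 3L),
        phiG = if (mode == "free") model$phiG else rep(NA_real_, 2L),
        epsRef = eps[1L], epsAlt = eps[2L], lambda = lambda,
        logLik = final, logLikTrace = trace,
        nIter = it, converged = converged, haltedEps = halted,
        logLiks = ll, posteriors = post, ploidy = m,
        sampleIds = ids, estimatedErrors = estimateErrors)
}
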