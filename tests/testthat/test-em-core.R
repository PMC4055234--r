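priorHWE <- function(psi) list(mode = "HWE", psi = psi)

test_that("E-step posteriors and expected counts follow the model", {
    # no data: the posterior is the HWE prior
    x <- SVCountSet(ref = 0, alt = 0)
    ll <- genotypeLogLik(x)
    st <- svpopgen:::.eStep(ll, svpopgen:::.priorMatrix(priorHWE(0.5), 2L),
                            0, 0, 2L, "S1")
    expect_equal(unname(st$post[1, ]), c(0.25, 0.5, 0.25))
    expect_equal(unname(st$Dg), c(0.25, 0.5, 0.25))

    # one reference draw, no errors: prior * likelihood = (0, .25, .25)
    x <- SVCountSet(ref = 1, alt = 0)
    ll <- genotypeLogLik(x, epsRef = 0, epsAlt = 0)
    st <- svpopgen:::.eStep(ll, svpopgen:::.priorMatrix(priorHWE(0.5), 2L),
                            1, 0, 2L, "S1")
    expect_equal(unname(st$post[1, ]), c(0, 0.5, 0.5))

    # expected individuals per class sum to the class sizes
    set.seed(201)
    x <- randomCountSet(40, mixedPloidy = TRUE)
    ll <- genotypeLogLik(x, epsRef = 0.01, epsAlt = 0.01)
    st <- svpopgen:::.eStep(ll,
        svpopgen:::.priorMatrix(priorHWE(0.3), ploidy(x)),
        unname(refCounts(x)), unname(altCounts(x)), ploidy(x), colnames(x))
    expect_equal(sum(st$Dg), sum(ploidy(x) == 2L))
    expect_equal(sum(st$Hg), sum(ploidy(x) == 1L))
    # count mass is fully attributed to the modeled classes
    expect_equal(st$R0 + st$R2 + st$C1r, sum(refCounts(x)))
    expect_equal(st$A0 + st$A2 + st$C1a, sum(altCounts(x)))
})

test_that("frequency M-step implements the published updates", {
    st <- list(Dg = c(10, 20, 70), Hg = c(0, 0), D = 100, H = 0)
    expect_equal(svpopgen:::.mStepFrequencies(st, "HWE")$psi, 0.2)

    st <- list(Dg = c(0, 0, 0), Hg = c(30, 70), D = 0, H = 100)
    expect_equal(svpopgen:::.mStepFrequencies(st, "HWE")$psi, 0.3)

    st <- list(Dg = c(25, 50, 25), Hg = c(0, 0), D = 100, H = 0)
    out <- svpopgen:::.mStepFrequencies(st, "free")
    expect_equal(out$psiG, c(0.25, 0.5, 0.25))

    st <- list(Dg = c(0, 0, 0), Hg = c(0, 0), D = 0, H = 0)
    expect_error(svpopgen:::.mStepFrequencies(st, "free"), "no individuals")
})

test_that("error M-step: closed forms at lambda = 1", {
    st <- list(R0 = 3, R2 = 997, A0 = 990, A2 = 10, C1r = 50, C1a = 70)
    e <- svpopgen:::.mStepErrors(st, lambda = 1, current = c(0.1, 0.1))
    expect_equal(unname(e), c(3 / 1000, 10 / 1000))
    # the closed form is also the grid argmax of Q (het term is constant)
    set.seed(202)
    for (i in 1:10) {
        A0 <- rexp(1, 1 / 500); A2 <- rexp(1, 1 / 20); C <- rexp(1, 1 / 100)
        closed <- A2 / (A0 + A2)
        if (closed >= 0.5) next
        expect_equal(gridQArgmax(A2, C, A0, 1), closed, tolerance = 1e-6)
    }
})

test_that("error M-step: quadratic solution matches the grid oracle", {
    e <- svpopgen:::.maxQ(Z = 5, C = 100, W = 900, mu = 4, fallback = 0)
    expect_lt(abs(e - gridQArgmax(5, 100, 900, 4)), 1e-6)

    set.seed(203)
    for (i in 1:40) {
        Z <- rexp(1, 1 / 30); C <- rexp(1, 1 / 200); W <- rexp(1, 1 / 800)
        mu <- exp(runif(1, -5, 5))
        got <- svpopgen:::.maxQ(Z, C, W, mu, fallback = 0)
        expect_lt(abs(min(got, 0.5) - gridQArgmax(Z, C, W, mu)), 1e-6)
    }
    # boundary case: no erroneous mass at all
    expect_lt(abs(min(svpopgen:::.maxQ(0, 100, 900, 4, fallback = 0), 0.5) -
                  gridQArgmax(0, 100, 900, 4)), 1e-6)
})

test_that("observed log-likelihood sums per-sample mixture logs", {
    # empty-count sample contributes log(1) = 0
    x0 <- SVCountSet(ref = 0, alt = 0)
    expect_equal(observedLogLik(x0, psi = 0.37, epsRef = 0.01,
                                epsAlt = 0.02, lambda = 2), 0)

    # single reference draw at psi = 0.5: 0.5 * 0.5 + 0.25 * 1 = 0.5
    x1 <- SVCountSet(ref = 1, alt = 0)
    expect_equal(observedLogLik(x1, psi = 0.5, epsRef = 0, epsAlt = 0),
                 log(0.5))

    # additivity over identical samples
    x8 <- SVCountSet(ref = rep(1, 8), alt = rep(0, 8))
    expect_equal(observedLogLik(x8, psi = 0.5, epsRef = 0, epsAlt = 0),
                 8 * log(0.5))
})

test_that("EM finds the boundary for an all-reference table", {
    x <- SVCountSet(ref = rep(5, 50), alt = rep(0, 50))
    fit <- svFit(x, epsRef = 0, epsAlt = 0)
    expect_lt(psiHat(fit), 1e-6)
    expect_true(fit@converged)
})

test_that("EM matches the ML of a symmetric two-sample table", {
    x <- SVCountSet(ref = c(2, 0), alt = c(0, 2))
    fit <- svFit(x, epsRef = 0, epsAlt = 0)
    expect_equal(psiHat(fit), 0.5, tolerance = 1e-6)
    expect_equal(psiHat(fit),
                 gridPsiML(c(2, 0), c(0, 2), c(2L, 2L)), tolerance = 1e-4)
})

test_that("EM matches grid-search maximum likelihood on small tables", {
    set.seed(204)
    for (i in 1:12) {
        mixed <- i %% 3 == 0
        x <- randomCountSet(sample(2:10, 1), mixedPloidy = mixed)
        if (all(totalCounts(x) == 0)) next
        er <- if (mixed) 0.01 else 0
        lam <- sample(c(0.5, 1, 2), 1)
        fit <- svFit(x, lambda = lam, epsRef = er, epsAlt = er)
        want <- gridPsiML(unname(refCounts(x)), unname(altCounts(x)),
                          ploidy(x), lambda = lam, er = er, ea = er)
        expect_equal(psiHat(fit), want, tolerance = 1e-4)
    }
})

test_that("free-mode EM beats an exhaustive coarse simplex grid", {
    set.seed(205)
    x <- randomCountSet(8)
    fit <- svFit(x, mode = "free", epsRef = 0.01, epsAlt = 0.01)
    best <- -Inf; bestG <- NULL
    for (p0 in seq(0.01, 0.97, by = 0.02)) {
        for (p1 in seq(0.01, 0.99 - p0, by = 0.02)) {
            g <- c(p0, p1, 1 - p0 - p1)
            llv <- observedLogLik(x, psiG = g, epsRef = 0.01, epsAlt = 0.01)
            if (llv > best) { best <- llv; bestG <- g }
        }
    }
    expect_gte(fit@logLik, best - 1e-8)
    expect_equal(genotypeFreqs(fit)$psiG, bestG, tolerance = 0.03,
                 ignore_attr = TRUE)
})

test_that("allele frequency is recovered from simulated low-coverage data", {
    set.seed(206)
    reps <- 30
    est <- replicate(reps, {
        s <- simulateCounts(n = 100, psi = 0.2, meanCoverage = 4,
                            flipError = 0.005, seed = sample.int(1e6, 1))
        psiHat(svFit(s$counts, epsRef = 0.005, epsAlt = 0.005))
    })
    se <- sd(est) / sqrt(reps)
    expect_lt(abs(mean(est) - 0.2), 3 * se + 1e-3)
})

test_that("an all-hemizygous table recovers the allele frequency", {
    set.seed(207)
    s <- simulateCounts(n = 600, psi = 0.35, meanCoverage = 4,
                        flipError = 0.005, ploidy = 1L, seed = 77)
    fit <- svFit(s$counts, epsRef = 0.005, epsAlt = 0.005)
    expect_lt(abs(psiHat(fit) - 0.35), 3 * sqrt(0.35 * 0.65 / 600) + 0.01)
})

test_that("extreme bias tolerates an order-of-magnitude misfit", {
    set.seed(208)
    est <- replicate(10, {
        s <- simulateCounts(n = 500, psi = 0.3, meanCoverage = 4,
                            lambda = 100, flipError = 0.005,
                            seed = sample.int(1e6, 1))
        psiHat(svFit(s$counts, lambda = 1000, epsRef = 0.005,
                     epsAlt = 0.005))
    })
    expect_lt(abs(mean(est) - 0.3), 0.03)
})

test_that("label-swap equivariance: psi maps to 1 - psi", {
    set.seed(209)
    s <- simulateCounts(n = 150, psi = 0.3, meanCoverage = 4, lambda = 2,
                        flipError = 0.01, seed = 5)
    x <- s$counts
    fit <- svFit(x, lambda = 2, epsRef = 0.01, epsAlt = 0.02)
    swapped <- SVCountSet(ref = unname(altCounts(x)),
                          alt = unname(refCounts(x)),
                          ploidy = ploidy(x), sampleIds = colnames(x))
    fit2 <- svFit(swapped, lambda = 1 / 2, epsRef = 0.02, epsAlt = 0.01)
    expect_equal(psiHat(fit2), 1 - psiHat(fit), tolerance = 1e-6)
})

test_that("the log-likelihood never decreases along the iterations", {
    set.seed(210)
    for (i in 1:8) {
        x <- randomCountSet(60, mixedPloidy = i > 6)
        fit <- suppressWarnings(
            svFit(x, lambda = sample(c(0.5, 1, 3), 1),
                  epsRef = 0.01, epsAlt = 0.01,
                  estimateErrors = i %% 2 == 0,
                  mode = if (i %% 3 == 0) "free" else "HWE"))
        if (length(fit@logLikTrace) > 1)
            expect_gte(min(diff(fit@logLikTrace)), -1e-9)
    }
})

test_that("error estimation halts when an update reaches 0.5", {
    # perfectly symmetric counts force the reference-error update to 0.5
    x <- SVCountSet(ref = rep(5, 30), alt = rep(5, 30))
    expect_warning(
        fit <- svFit(x, epsRef = 0.1, epsAlt = 0.1, estimateErrors = TRUE),
        "co-estimation")
    expect_true(fit@haltedEps)
    expect_false(fit@converged)
    # the reported error rates are the last valid ones, still below 0.5
    expect_lt(fit@epsRef, 0.5)
})

test_that("co-estimation warns on thin data and degenerate samples error", {
    set.seed(211)
    s <- simulateCounts(n = 10, psi = 0.5, meanCoverage = 2, seed = 3)
    expect_warning(svFit(s$counts, estimateErrors = TRUE), "recommended")

    # a hemizygote showing both alleles is impossible without errors
    x <- SVCountSet(ref = 1, alt = 1, ploidy = 1L, sampleIds = "HEMI1")
    expect_error(svFit(x, epsRef = 0, epsAlt = 0), "HEMI1")
})

test_that("estimation is refused without any counts", {
    x <- SVCountSet(ref = c(0, 0), alt = c(0, 0))
    expect_error(svFit(x), "at least one")
})
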