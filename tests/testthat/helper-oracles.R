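# Independent oracles used across the test files. Everything here evaluates
# the model by direct arithmetic (plain products, exhaustive grids), not
# through the package's log-space / EM code paths.

# Direct-product genotype likelihoods for one individual (vector over
# g = 0..2; hemizygotes get their two genotypes in slots 1:2 and 0 in 3).
oracleGenoLik <- function(l, a, m, lambda = 1, er = 0, ea = 0) {
    pw <- function(b, e) if (e == 0) 1 else b^e
    k <- l + a
    if (m == 2L) {
        c(pw(er, l) * pw(1 - ea, a),
          (1 / (1 + lambda))^k * pw(er + lambda * (1 - er), l) *
              pw((1 - ea) + lambda * ea, a),
          pw(1 - er, l) * pw(ea, a))
    } else {
        c(pw(er, l) * pw(1 - ea, a), pw(1 - er, l) * pw(ea, a), 0)
    }
}

# Total log-likelihood over a psi grid (HWE prior), direct products.
# Returns the grid and the log-likelihood at each point.
oraclePsiProfile <- function(ref, alt, ploidy, lambda = 1, er = 0, ea = 0,
                             step = 1e-5) {
    ps <- seq(step, 1 - step, by = step)
    L <- t(mapply(oracleGenoLik, ref, alt, ploidy,
                  MoreArgs = list(lambda = lambda, er = er, ea = ea)))
    dip <- ploidy == 2L
    tot <- 0
    if (any(dip)) {
        P <- cbind(ps^2, 2 * ps * (1 - ps), (1 - ps)^2)
        tot <- tot + rowSums(log(P %*% t(L[dip, , drop = FALSE])))
    }
    if (any(!dip)) {
        P <- cbind(ps, 1 - ps)
        tot <- tot + rowSums(log(P %*% t(L[!dip, 1:2, drop = FALSE])))
    }
    list(psi = ps, logLik = tot)
}

gridPsiML <- function(ref, alt, ploidy, lambda = 1, er = 0, ea = 0,
                      step = 1e-5) {
    pr <- oraclePsiProfile(ref, alt, ploidy, lambda, er, ea, step)
    pr$psi[which.max(pr$logLik)]
}

# The eps-part of the expected complete-data log-likelihood,
# Q(x) = Z log x + C log(x + mu (1 - x)) + W log(1 - x), with 0 log 0 = 0.
oracleQ <- function(x, Z, C, W, mu) {
    t1 <- if (Z == 0) 0 else Z * log(x)
    t3 <- if (W == 0) 0 else W * log(1 - x)
    t1 + C * log(x + mu * (1 - x)) + t3
}

# Dense grid argmax of Q on [0, 0.5]; Q is concave so a coarse pass plus a
# fine refinement around the coarse winner is exhaustive.
gridQArgmax <- function(Z, C, W, mu) {
    lo <- if (Z == 0) 0 else 1e-9
    xs <- seq(lo, 0.5, length.out = 50001)
    q <- oracleQ(xs, Z, C, W, mu)
    best <- xs[which.max(q)]
    span <- xs[2] - xs[1]
    xs2 <- seq(max(lo, best - span), min(0.5, best + span), by = 1e-8)
    xs2[which.max(oracleQ(xs2, Z, C, W, mu))]
}

# Random valid count tables for property tests.
randomCountSet <- function(n, meanCoverage = 3, mixedPloidy = FALSE) {
    k <- stats::rpois(n, meanCoverage)
    l <- stats::rbinom(n, k, stats::runif(1, 0.2, 0.8))
    pl <- if (mixedPloidy) sample(c(1L, 2L), n, replace = TRUE) else 2L
    SVCountSet(ref = l, alt = k - l, ploidy = pl,
               sampleIds = sprintf("R%03d", seq_len(n)))
}
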