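---
title: "Genotype-free population genetics of structural variants: the model behind svpopgen"
author: "svpopgen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-free population genetics of structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpopgen)
```

## The problem

Bi-allelic structural variants (deletions, insertions, inversions) can be
observed in sequence data through split reads or discordant paired ends.
After the discovery phase, what reaches the analyst is, per individual, a
pair of counts: how many times the reference allele and how many times the
alternative allele were observed at the locus. At low coverage these counts
rarely determine the genotype, and — unlike for SNPs — the two alleles of a
heterozygote are generally *not* sampled with equal probability: read
mappers favour concordant (reference) alignments, and the two alleles
differ in how detectable they are. svpopgen estimates population parameters
directly from the counts, treating genotypes as missing data, so that
nothing ever needs to be genotyped.

## The likelihood

Each individual has ploidy $m \in \{1, 2\}$ and genotype
$g \in \{0, \dots, m\}$, the number of **reference** alleles it carries. We
write $k$ for its total count, $l$ for its reference count, and $\psi$ for
the population frequency of the **alternative** allele (so under
Hardy–Weinberg equilibrium a diploid has prior
$(\psi^2,\, 2\psi(1-\psi),\, (1-\psi)^2)$ over $g = 0, 1, 2$).

Three nuisance parameters describe the observation process:

* $\lambda$ — the *allele sampling bias*: the odds that a single draw from
  a diploid heterozygote reports the reference allele. $\lambda = 1$ is the
  SNP-like unbiased case; structural variants observed via breakpoint
  evidence routinely have $\lambda$ several orders of magnitude away
  from 1.
* $\epsilon_r$, $\epsilon_a$ — the frequencies of erroneous counts among
  reference-labeled and alternative-labeled observations. These summarise
  count quality in aggregate; if per-observation qualities are available,
  quality-weighted "effective" (non-integer) counts can be supplied
  instead.

The genotype likelihoods are

$$\mathcal{L}(0) = \epsilon_r^{\,l}\,(1-\epsilon_a)^{k-l}, \qquad
  \mathcal{L}(2) = (1-\epsilon_r)^{\,l}\,\epsilon_a^{k-l},$$

$$\mathcal{L}(1) = \left(\frac{1}{1+\lambda}\right)^{k}
  \bigl(\epsilon_r + \lambda(1-\epsilon_r)\bigr)^{l}
  \bigl((1-\epsilon_a) + \lambda\epsilon_a\bigr)^{k-l},$$

with hemizygous genotypes taking the likelihoods of the corresponding
homozygotes. At $\lambda = 1$ the heterozygote reduces to $(1/2)^k$ for any
error rates. Everything is computed in log space with the convention
$0^0 = 1$, so a zero-count individual is uninformative rather than
degenerate.

One modelling subtlety is worth stating openly: for
$\epsilon_r \neq \epsilon_a$ the implied per-count label probabilities in a
homozygote ($\epsilon_r$ for a stray reference label, $1-\epsilon_a$ for a
correct alternative label, say) do not sum to one. They are *conditional
error frequencies*, not flip probabilities, and the likelihood is used
exactly as written. A practical consequence is that when both error rates
are co-estimated on data whose homozygote classes are very unbalanced, the
pooled maximizer can drift away from the per-class error fraction; the
symmetric case $\epsilon_r = \epsilon_a$ (which is how the bundled
simulator generates errors) is exactly a per-count Bernoulli flip and is
recovered correctly. This is one of several reasons the package recommends
a-priori error rates whenever coverage is below 4 or fewer than 100
individuals are available, and warns otherwise.

$\lambda$ is deliberately **not** estimated by the EM: spending a degree of
freedom on it would ruin the estimation of extreme allele frequencies in
the presence of errors, and it can be obtained externally (see below).

## The EM algorithm

Treating genotypes as missing data, the E-step computes each individual's
posterior $P(g \mid \text{data}) \propto P(g \mid \text{model})\,
\mathcal{L}(g)$ and accumulates expected class sizes: $D_g$ (diploids per
genotype), $H_g$ (hemizygotes), and the expected count masses $R_0, R_2$
(reference counts in the all-alternative and all-reference classes),
$A_0, A_2$ (alternative counts in those classes) and $C_{1r}, C_{1a}$
(reference/alternative counts in diploid heterozygotes).

The M-step updates, under HWE,

$$\psi' = \frac{2D_0 + D_1 + H_0}{2(D_0 + D_1 + D_2) + H_0 + H_1},$$

(the numerator counts alternative alleles because $g$ counts reference
ones), or, without the equilibrium assumption, $\psi_g' = D_g / D$ and
$\phi_g' = H_g / H$ — the free diploid and hemizygous genotype frequencies.

When error rates are co-estimated and $\lambda = 1$ the maximizers are the
closed forms $\epsilon_r' = R_0 / (R_0 + R_2)$ and
$\epsilon_a' = A_2 / (A_0 + A_2)$ (heterozygote counts carry no information
about the errors at $\lambda = 1$). For $\lambda \neq 1$ the
$\epsilon$-dependent part of the expected complete-data log-likelihood is,
for the reference rate,

$$Q_r(x) = R_0 \log x + C_{1r} \log\bigl(x + \lambda(1 - x)\bigr)
  + R_2 \log(1 - x),$$

a concave function whose stationary condition is a quadratic; the package
solves it analytically (the alternative rate is the same problem with
$\lambda \mapsto 1/\lambda$), and the test suite checks the solution
against a dense grid search. Erroneous counts are assumed to be a minority:
if an update reaches $0.5$, estimation halts, the last valid estimates are
returned and the fit is flagged (`haltedEps`); downstream consumers should
treat such fits as unreliable rather than silently reuse them.

### Numerical choices

* Initialization is the interior point $\psi^{(0)} = 0.5$ (free mode:
  $(1/4, 1/2, 1/4)$ and $(1/2, 1/2)$), avoiding the absorbing boundaries.
  On realistic data the likelihood has a single interior maximum, and the
  grid-search cross-checks in the test suite confirm the fixed point does
  not depend on the start.
* Convergence is declared when the observed-data log-likelihood changes by
  less than `tol = 1e-8`, with a cap of 10&nbsp;000 iterations. Each
  iteration only reweights an $n \times 3$ matrix (the likelihood matrix is
  constant while the error rates are fixed), so even slow, low-information
  fits cost milliseconds.
* If $\hat\psi$ lands exactly on 0 or 1 the boundary is absorbing and
  iteration stops there.
* Individuals with $k = 0$ are retained: they are harmless at the fixed
  point under HWE, and the free-mode denominators $D$ and $H$ are defined
  over all individuals.
* A sample whose every genotype has zero posterior mass (e.g. a hemizygote
  showing both labels when $\epsilon = 0$) aborts the fit with an error
  naming the sample — it indicates a mis-specified error model, not a
  numerical accident.
* EM ascent (the log-likelihood never decreasing by more than $10^{-9}$)
  is asserted in the tests across HWE/free, biased/unbiased and
  fixed/co-estimated configurations.

## Posteriors, genotype calls and derived statistics

Genotype posteriors reweight the likelihoods by the fitted frequencies,
$P(g \mid \text{data}) = \mathcal{L}(g) P(g \mid \hat\psi) / \sum_{g'}
\mathcal{L}(g') P(g' \mid \hat\psi)$ (or with $\hat\psi_g / \hat\phi_g$ in
place of the HWE prior). The most *probable* genotype (posterior argmax) is
recommended over the most *likely* one (likelihood argmax) because it
borrows the population frequency information; exact posterior ties are
broken toward the heterozygote, then toward the lower genotype, which
minimizes the expected allele-count error and keeps calls deterministic.

From the fits follow: heterozygosity $\hat\psi_1$ (the free-mode
heterozygote frequency), the inbreeding coefficient
$\hat F = 1 - \hat\psi_1 / (2\hat\psi(1-\hat\psi))$, and between-population
differentiation. For $F_{ST}$ the package implements Hudson's
two-population, single-locus estimator

$$\hat F_{ST} = \frac{(p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1}
  - \frac{p_2(1-p_2)}{n_2 - 1}}{p_1(1 - p_2) + p_2(1 - p_1)},$$

a deliberate design choice among the several classical variants: it is
unbiased under the island model, independent of the two sample sizes'
ratio, and the one most often recommended for pairwise comparisons from
allele frequencies. The choice is documented here precisely because the
method family only prescribes "an $F_{ST}$ from allele frequencies".

Two likelihood-ratio tests are provided. The HWE test compares the free
fit against the HWE fit: $2(\ell_1 - \ell_0)$ against $\chi^2_1$ when all
individuals are diploid, $\chi^2_2$ when hemizygous genotype frequencies
are estimated too. The population-difference test fits two samples
separately and pooled: $2(\ell_a + \ell_b - \ell_0)$ against $\chi^2_1$.
In both tests $\lambda$, $\epsilon_r$ and $\epsilon_a$ are shared across
the fits being compared; co-estimating errors per population would change
the degrees of freedom and is therefore refused rather than silently
accepted.

## Choosing lambda

Two helpers translate external information into a $\lambda$ value:

* `lambdaFromKnownHets()` pools the counts of individuals known to be
  heterozygous by independent evidence and returns the reference/alternative
  ratio, which estimates the odds directly.
* `lambdaFromSize()` evaluates empirical log–log regressions of bias on
  variant length — $\log\lambda = -4.22 + 0.94\log(\text{size})$ for
  deletions, $\log\lambda = 3.84 - 0.87\log(\text{size})$ for insertions,
  $\lambda = 1$ for inversions. The natural-log convention is assumed
  (the source material plots "logarithmic scales" without naming a base);
  since the regressions explain well under half of the variance and are
  offered only as rough priors, and since values within a factor of two of
  the truth cause only minor frequency biases, the base ambiguity is
  tolerable and is flagged on the returned value.

Truly infinite bias (one allele undetectable by the sequencing layout)
must be approximated by a large finite value such as $10^6$: at low
coverage all sufficiently extreme $\lambda$ behave identically, because no
small sample of draws ever shows the disfavoured allele.

## What the simulator does and does not emulate

`simulateCounts()` reproduces the design under which this class of
estimator is conventionally validated: HWE genotypes at a chosen $\psi$
(or explicit genotype frequencies), per-individual depth
$k \sim \text{Poisson}(\bar c)$, reference draws from heterozygotes with
probability $\lambda/(1+\lambda)$, and independent symmetric label flips at
rate 0.005 by default — the error level of the published simulation study.
Under symmetric flips the likelihood model with
$\epsilon_r = \epsilon_a = $ flip rate is exactly the per-count law, so
simulation-based tests probe estimation, not model mismatch. Deliberately
not offered: asymmetric error generation (no generative law is defined for
conditional error frequencies), read-level simulation, reference
sequences, linkage between sites, and coverage distributions other than
Poisson (the genotype likelihoods do not depend on the depth distribution
anyway).

Consequently, passing tests demonstrate correct inference *under the
stated observation model*; they cannot certify behaviour under real-data
pathologies the model excludes, such as systematically mislabelled
samples, allele-specific error rates, or copy-number states beyond two.

## Problem sizes used in the validation suite

The statistical checks in `tests/testthat/test-acceptance.R` use the
package's own choice of study sizes: 5&nbsp;000 individuals for the
coverage-1 genotype-error bound; a $4 \times 4$ grid of
$\psi \in \{0.01, 0.05, 0.2, 0.5\}$ and mean coverage
$\{0.2, 1, 2, 4\}$ with 100 replicates of $n = 100$ for unbiasedness
(excluding the known failure zone $\psi \le 0.01$ with coverage $< 0.5$);
50 replicates of $n = 1000$ at coverage 4 for bias-misspecification
robustness at $\lambda \in \{0.01, 1, 100\}$ fitted with $\lambda$,
$\lambda/2$ and $2\lambda$; 50 random small tables against a $10^{-5}$-step
likelihood grid for EM/ML agreement; and 1&nbsp;000 replicates each for the
type-I calibration of the two likelihood-ratio tests at $n = 100$,
coverage 4, with $\psi$ drawn uniformly from $(0.1, 0.9)$ per replicate
(kept away from the boundaries where small-sample chi-square asymptotics,
not the implementation, dominate).
The unbiasedness criterion tests every grid cell at two standard errors of
the replicate mean, so even a perfectly unbiased estimator has a
non-trivial familywise chance of a marginal excursion; the fixed seed makes
any such excursion reproducible rather than flaky.

## A worked example

```{r example}
sim <- simulateCounts(n = 300, psi = 0.3, meanCoverage = 2, lambda = 5,
                      flipError = 0.005, seed = 1)
fit <- svFit(sim$counts, lambda = 5, epsRef = 0.005, epsAlt = 0.005)
fit
hweTest(sim$counts, lambda = 5, epsRef = 0.005, epsAlt = 0.005)
table(called = mostProbableGenotypes(fit), truth = sim$genotypes)
```

## Known limitations

* Bi-allelic variants only; overlapping or multi-allelic rearrangements
  are out of scope.
* $\lambda$ is an input, not an estimate; a badly wrong $\lambda$ (in the
  direction opposite to the true bias, especially) degrades genotype calls
  more than frequency estimates.
* Error co-estimation is only trustworthy with adequate information
  (coverage $\ge 4$ and $n \ge 100$ as a rule of thumb), and inherits the
  unnormalized-likelihood caveat above.
* The LRTs rely on large-sample $\chi^2$ asymptotics; at very small $n$ or
  extreme frequencies the calibration degrades as for any such test.
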