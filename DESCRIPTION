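Package: svpopgen
Title: Population Genetics of Bi-Allelic Structural Variants from Allele Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood estimation of allele and genotype frequencies,
    genotype posterior probabilities, and likelihood-ratio tests for
    bi-allelic structural variants from per-individual counts of reference
    and alternative allele observations. An expectation-maximization
    algorithm handles arbitrarily strong allele sampling bias in
    heterozygotes (reference bias), count error rates that may be fixed or
    co-estimated, and mixed diploid/hemizygous samples, making low-coverage
    population analyses possible without calling genotypes first. Includes
    Hardy-Weinberg and population-differentiation likelihood-ratio tests,
    heterozygosity, inbreeding coefficient and Hudson's F_ST, helpers to
    choose the sampling-bias parameter, and a simulator of count tables with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
biocViews: StructuralVariation, PopulationGenetics, Genetics, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
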