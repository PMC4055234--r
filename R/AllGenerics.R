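#' @rdname SVCountSet
#' @export
setGeneric("refCounts", function(x) standardGeneric("refCounts"))

#' @rdname SVCountSet
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))

#' @rdname SVCountSet
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname SVCountSet
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname SVFit-accessors
#' @export
setGeneric("psiHat", function(object) standardGeneric("psiHat"))

#' @rdname SVFit-accessors
#' @export
setGeneric("genotypeFreqs", function(object) standardGeneric("genotypeFreqs"))

#' @rdname SVFit-accessors
#' @export
setGeneric("errorRates", function(object) standardGeneric("errorRates"))

#' @rdname SVFit-accessors
#' @export
setGeneric("genotypeLikelihoods",
    function(object) standardGeneric("genotypeLikelihoods"))

#' @rdname SVFit-accessors
#' @export
setGeneric("genotypePosteriors",
    function(object, ...) standardGeneric("genotypePosteriors"))

#' @rdname SVFit-accessors
#' @export
setGeneric("mostProbableGenotypes",
    function(object, ...) standardGeneric("mostProbableGenotypes"))

#' @rdname heterozygosity
#' @export
setGeneric("heterozygosity", function(object) standardGeneric("heterozygosity"))
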