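## Generics for the package's S4 data containers.

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @export
setGeneric("hasPhase", function(x) standardGeneric("hasPhase"))

#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @export
setGeneric("chroms", function(x) standardGeneric("chroms"))

#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @export
setGeneric("popOf", function(x, samples) standardGeneric("popOf"))

#' @export
setGeneric("samplesOf", function(x, population) standardGeneric("samplesOf"))

#' @export
setGeneric("popsWithRole", function(x, role) standardGeneric("popsWithRole"))

#' @export
setGeneric("hybridDonors", function(x, population) standardGeneric("hybridDonors"))

#' @export
setGeneric("addScores", function(x) standardGeneric("addScores"))

#' @export
setGeneric("donorNames", function(x) standardGeneric("donorNames"))

#' @export
setGeneric("dosageMatrix", function(x, donor) standardGeneric("dosageMatrix"))

#' @export
setGeneric("donorMeans", function(x) standardGeneric("donorMeans"))
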