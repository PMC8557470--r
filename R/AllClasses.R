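#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Biallelic SNP genotypes with optional phase
#'
#' Container for a matrix of biallelic SNP genotypes (sites x samples,
#' allele dosages in \{0, 1, 2, NA\}) together with the site coordinates
#' (1-based, as in VCF), REF/ALT alleles, and optionally the phased
#' haplotypes (sites x 2*samples, alleles in \{0, 1, NA\}).
#'
#' Invariants enforced by the validity method: all sites are biallelic
#' SNPs (single-character REF != ALT); positions strictly increase within
#' each chromosome; wherever both haplotype alleles of a sample are
#' non-missing, their sum equals the genotype.
#'
#' @slot genotypes integer matrix, sites x samples, values 0/1/2/NA.
#' @slot haplotypes integer matrix sites x (2*samples) with columns
#'   `<sample>_1`, `<sample>_2`, values 0/1/NA; or NULL when unphased.
#'   Entries may be NA for individual unphased records.
#' @slot variants [GenomicRanges::GRanges] of width 1 with metadata
#'   columns `ref` and `alt`.
#'
#' @examples
#' gd <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2, 2,
#'                           dimnames = list(NULL, c("s1", "s2"))),
#'                    chrom = c("chr1", "chr1"), pos = c(10L, 20L),
#'                    ref = c("A", "C"), alt = c("G", "T"))
#' nSites(gd)
#' @export
setClass("GenotypeData",
  representation(genotypes = "matrix",
                 haplotypes = "matrixOrNULL",
                 variants = "GRanges"))

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  v <- object@variants
  msg <- character()
  if (nrow(g) != length(v))
    msg <- c(msg, "number of genotype rows must equal number of variants")
  if (is.null(colnames(g)) && ncol(g) > 0)
    msg <- c(msg, "genotype columns must be named by sample")
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (length(v)) {
    ref <- S4Vectors::mcols(v)$ref
    alt <- S4Vectors::mcols(v)$alt
    if (is.null(ref) || is.null(alt)) {
      msg <- c(msg, "variants must carry ref and alt metadata columns")
    } else if (any(nchar(ref) != 1L) || any(nchar(alt) != 1L) ||
               any(ref == alt)) {
      msg <- c(msg, "all sites must be biallelic SNPs (1-bp ref != alt)")
    }
    sp <- split(GenomicRanges::start(v), as.character(GenomicRanges::seqnames(v)))
    if (any(vapply(sp, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must strictly increase within each chromosome")
  }
  h <- object@haplotypes
  if (!is.null(h)) {
    if (nrow(h) != nrow(g) || ncol(h) != 2L * ncol(g))
      msg <- c(msg, "haplotypes must be sites x (2*samples)")
    hb <- h[!is.na(h)]
    if (length(hb) && !all(hb %in% c(0L, 1L)))
      msg <- c(msg, "haplotype alleles must be 0, 1 or NA")
    if (ncol(g) > 0 && nrow(g) > 0) {
      hs <- h[, seq(1L, ncol(h), by = 2L), drop = FALSE] +
            h[, seq(2L, ncol(h), by = 2L), drop = FALSE]
      ok <- is.na(hs) | is.na(g) | hs == g
      if (!all(ok))
        msg <- c(msg, "genotype must equal the sum of the two haplotype alleles")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param genotypes sites x samples matrix of allele dosages (0/1/2/NA);
#'   column names are the sample identifiers.
#' @param chrom chromosome label per site.
#' @param pos 1-based position per site (bp, VCF convention).
#' @param ref,alt single-character reference/alternate alleles per site.
#' @param haplotypes optional sites x (2*samples) matrix of phased alleles.
#' @return a [GenotypeData-class] object.
#' @export
GenotypeData <- function(genotypes, chrom, pos, ref, alt, haplotypes = NULL) {
  storage.mode(genotypes) <- "integer"
  if (!is.null(haplotypes)) {
    storage.mode(haplotypes) <- "integer"
    if (is.null(colnames(haplotypes)))
      colnames(haplotypes) <- paste0(rep(colnames(genotypes), each = 2L),
                                     c("_1", "_2"))
  }
  v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(pos), width = 1L))
  S4Vectors::mcols(v)$ref <- as.character(ref)
  S4Vectors::mcols(v)$alt <- as.character(alt)
  new("GenotypeData", genotypes = genotypes, haplotypes = haplotypes,
      variants = v)
}

#' @describeIn GenotypeData number of sites
#' @param x a GenotypeData object
#' @export
setMethod("nSites", "GenotypeData", function(x) nrow(x@genotypes))

#' @describeIn GenotypeData number of samples
#' @export
setMethod("nSamples", "GenotypeData", function(x) ncol(x@genotypes))

#' @describeIn GenotypeData sample identifiers
#' @export
setMethod("sampleIds", "GenotypeData", function(x) colnames(x@genotypes))

#' @describeIn GenotypeData genotype matrix (sites x samples)
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@genotypes)

#' @describeIn GenotypeData haplotype matrix or NULL
#' @export
setMethod("haplotypes", "GenotypeData", function(x) x@haplotypes)

#' @describeIn GenotypeData TRUE when phased haplotypes are stored
#' @export
setMethod("hasPhase", "GenotypeData", function(x) !is.null(x@haplotypes))

#' @describeIn GenotypeData site coordinates as GRanges
#' @export
setMethod("variants", "GenotypeData", function(x) x@variants)

#' @describeIn GenotypeData 1-based positions
#' @export
setMethod("positions", "GenotypeData",
          function(x) GenomicRanges::start(x@variants))

#' @describeIn GenotypeData chromosome label per site
#' @export
setMethod("chroms", "GenotypeData",
          function(x) as.character(GenomicRanges::seqnames(x@variants)))

#' @describeIn GenotypeData reference alleles
#' @export
setMethod("refAllele", "GenotypeData",
          function(x) S4Vectors::mcols(x@variants)$ref)

#' @describeIn GenotypeData alternate alleles
#' @export
setMethod("altAllele", "GenotypeData",
          function(x) S4Vectors::mcols(x@variants)$alt)

#' @describeIn GenotypeData subset by site (i) and/or sample (j)
#' @param i site indices
#' @param j sample indices (numeric, logical or sample names)
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSites(x))
  if (missing(j)) j <- seq_len(nSamples(x))
  if (is.character(j)) j <- match(j, sampleIds(x))
  if (is.logical(j)) j <- which(j)
  h <- x@haplotypes
  if (!is.null(h)) {
    hj <- as.vector(rbind(2L * j - 1L, 2L * j))
    h <- h[i, hj, drop = FALSE]
  }
  new("GenotypeData", genotypes = x@genotypes[i, j, drop = FALSE],
      haplotypes = h, variants = x@variants[i])
})

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d site(s) x %d sample(s)%s\n",
              nSites(object), nSamples(object),
              if (hasPhase(object)) ", phased" else ""))
  if (nSites(object)) {
    ch <- unique(chroms(object))
    cat(sprintf("  chromosomes: %s\n", paste(head(ch, 5), collapse = ", ")))
  }
})

#' Sample-to-population map with analysis roles
#'
#' Maps each sample to a population label, each population to a set of
#' analysis roles (P1, P2, P3, O, donorA, donorB, hybrid, none), and each
#' hybrid population to its two donor panels.  The four-taxon roles
#' P1/P2/P3/O must be carried by disjoint populations.
#'
#' @slot assignments named character vector: sample -> population.
#' @slot roles named list: population -> character vector of roles.
#' @slot donors named list: hybrid population -> c(donorA=, donorB=).
#' @export
setClass("PopMap",
  representation(assignments = "character", roles = "list", donors = "list"))

.valid_roles <- c("P1", "P2", "P3", "O", "donorA", "donorB", "hybrid", "none")

setValidity("PopMap", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)) ||
      anyDuplicated(names(object@assignments)))
    msg <- c(msg, "samples must be uniquely named")
  allroles <- unlist(object@roles)
  if (length(allroles) && !all(allroles %in% .valid_roles))
    msg <- c(msg, sprintf("roles must be among: %s",
                          paste(.valid_roles, collapse = ", ")))
  for (r in c("P1", "P2", "P3", "O")) {
    hit <- names(object@roles)[vapply(object@roles, function(x) r %in% x,
                                      logical(1))]
    if (length(hit) > 1)
      msg <- c(msg, sprintf("role %s assigned to more than one population", r))
  }
  taxa <- lapply(c("P1", "P2", "P3", "O"), function(r)
    names(object@roles)[vapply(object@roles, function(x) r %in% x, logical(1))])
  taxa <- unlist(taxa)
  if (anyDuplicated(taxa))
    msg <- c(msg, "P1, P2, P3 and O must be disjoint populations")
  for (h in names(object@donors)) {
    d <- object@donors[[h]]
    if (length(d) != 2L || is.null(names(d)) ||
        !setequal(names(d), c("donorA", "donorB")))
      msg <- c(msg, sprintf("hybrid %s must name exactly donorA and donorB", h))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PopMap
#'
#' @param samples sample identifiers.
#' @param pops population label per sample.
#' @param roles named list population -> character vector of roles
#'   (subset of P1, P2, P3, O, donorA, donorB, hybrid, none).
#' @param donors named list: hybrid population -> c(donorA =, donorB =).
#' @return a [PopMap-class] object.
#' @export
PopMap <- function(samples, pops, roles = list(), donors = list()) {
  new("PopMap", assignments = setNames(as.character(pops),
                                       as.character(samples)),
      roles = roles, donors = donors)
}

#' @describeIn PopMap population labels present in the map
#' @param x a PopMap
#' @export
setMethod("populations", "PopMap",
          function(x) unique(unname(x@assignments)))

#' @describeIn PopMap population of each given sample
#' @param samples sample identifiers
#' @export
setMethod("popOf", "PopMap", function(x, samples) {
  out <- x@assignments[samples]
  if (anyNA(out)) .stopf("sample(s) absent from population map: %s",
                         paste(samples[is.na(out)], collapse = ", "))
  unname(out)
})

#' @describeIn PopMap samples belonging to a population
#' @param population population label
#' @export
setMethod("samplesOf", "PopMap", function(x, population) {
  if (!population %in% x@assignments)
    .stopf("population '%s' absent from population map", population)
  names(x@assignments)[x@assignments == population]
})

#' @describeIn PopMap populations carrying a role
#' @param role one of P1, P2, P3, O, donorA, donorB, hybrid, none
#' @export
setMethod("popsWithRole", "PopMap", function(x, role) {
  names(x@roles)[vapply(x@roles, function(r) role %in% r, logical(1))]
})

#' @describeIn PopMap the two donor panels of a hybrid population
#' @export
setMethod("hybridDonors", "PopMap", function(x, population) {
  d <- x@donors[[population]]
  if (is.null(d)) .stopf("no donor panels recorded for '%s'", population)
  d
})

setMethod("show", "PopMap", function(object) {
  tab <- table(object@assignments)
  cat(sprintf("PopMap: %d sample(s), %d population(s)\n",
              length(object@assignments), length(tab)))
  for (p in names(tab)) {
    r <- object@roles[[p]]
    cat(sprintf("  %s: n=%d%s\n", p, tab[[p]],
                if (length(r)) paste0(" [", paste(r, collapse = ","), "]")
                else ""))
  }
})

#' Per-site local-ancestry dosages for a hybrid population
#'
#' Stores per-sample posterior donor-B dosages from the local-ancestry
#' HMM (per-haplotype dosages averaged over the two haplotypes, so values
#' lie in [0, 1] and donor-A dosage is the complement), the per-site
#' population-mean dosages, and the allele dosage difference
#' ADD = |mean dosage donorA - mean dosage donorB|.
#'
#' @slot chrom chromosome label per site.
#' @slot pos 1-based position per site.
#' @slot samples sample identifiers (hybrid individuals).
#' @slot donors the two donor population labels, c(donorA, donorB).
#' @slot dosageB sites x samples matrix of donor-B dosages in [0, 1].
#' @slot meanA,meanB per-site population means of the two donor dosages.
#' @slot add per-site ADD scores in [0, 1].
#' @export
setClass("DosageTrack",
  representation(chrom = "character", pos = "integer", samples = "character",
                 donors = "character", dosageB = "matrix",
                 meanA = "numeric", meanB = "numeric", add = "numeric"))

setValidity("DosageTrack", function(object) {
  msg <- character()
  d <- object@dosageB
  if (nrow(d) != length(object@pos))
    msg <- c(msg, "dosageB must have one row per site")
  if (ncol(d) != length(object@samples))
    msg <- c(msg, "dosageB must have one column per sample")
  dd <- d[is.finite(d)]
  if (length(dd) && (min(dd) < -1e-9 || max(dd) > 1 + 1e-9))
    msg <- c(msg, "dosages must lie in [0, 1]")
  if (length(object@donors) != 2L)
    msg <- c(msg, "exactly two donors required")
  s <- abs(object@meanA + object@meanB - 1)
  if (length(s) && any(is.finite(s) & s > 1e-9))
    msg <- c(msg, "per-site mean dosages must sum to one over donors")
  a <- object@add[is.finite(object@add)]
  if (length(a) && (min(a) < -1e-9 || max(a) > 1 + 1e-9))
    msg <- c(msg, "ADD must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn DosageTrack per-site ADD scores
#' @param x a DosageTrack
#' @export
setMethod("addScores", "DosageTrack", function(x) x@add)

#' @describeIn DosageTrack donor population labels (A, B)
#' @export
setMethod("donorNames", "DosageTrack", function(x) x@donors)

#' @describeIn DosageTrack per-sample dosage matrix for one donor
#' @param donor donor label or "A"/"B"
#' @export
setMethod("dosageMatrix", "DosageTrack", function(x, donor) {
  if (donor %in% c("B", x@donors[2])) x@dosageB
  else if (donor %in% c("A", x@donors[1])) 1 - x@dosageB
  else .stopf("unknown donor '%s'", donor)
})

#' @describeIn DosageTrack per-site population-mean dosages (data.frame)
#' @export
setMethod("donorMeans", "DosageTrack", function(x) {
  data.frame(chrom = x@chrom, pos = x@pos, meanA = x@meanA, meanB = x@meanB,
             add = x@add)
})

#' @describeIn DosageTrack positions of the scored sites
#' @export
setMethod("positions", "DosageTrack", function(x) x@pos)

#' @describeIn DosageTrack sample identifiers
#' @export
setMethod("sampleIds", "DosageTrack", function(x) x@samples)

setMethod("show", "DosageTrack", function(object) {
  cat(sprintf("DosageTrack: %d site(s), %d sample(s), donors %s/%s\n",
              length(object@pos), length(object@samples),
              object@donors[1], object@donors[2]))
  if (length(object@add))
    cat(sprintf("  ADD mean %.3f, q75 %.3f, max %.3f\n",
                mean(object@add, na.rm = TRUE),
                quantile(object@add, 0.75, na.rm = TRUE, names = FALSE),
                max(object@add, na.rm = TRUE)))
})

#' Ground truth of a simulated cohort
#'
#' Records everything the generator planted: the true per-site donor-B
#' ancestry dosage of every sample, the introgressed tract (0-based
#' half-open, matching the window convention of the scan output), the
#' sweep focal site, the balancing-selection loci, and the true
#' per-population allele frequencies.
#'
#' @slot chrom chromosome label of the simulated sequence.
#' @slot pos 1-based position of every simulated site.
#' @slot dosageB sites x samples true donor-B dosages (donor-A dosage is
#'   the complement; NA for the outgroup, whose ancestry is neither donor).
#' @slot tract numeric c(start, end), 0-based half-open, or NULL-like
#'   empty vector when no tract was planted.
#' @slot carrierPop hybrid population carrying the tract ("" if none).
#' @slot sweepPos 1-based position of the sweep focal site (0 if none).
#' @slot bsLoci data.frame with columns pos (1-based) and kind
#'   ("shared" or "tract").
#' @slot popFreqs sites x populations true alternate-allele frequencies.
#' @slot altIsDerived logical per site; TRUE wherever the alternate
#'   allele is the derived allele (always TRUE for this generator).
#' @slot seed the generator seed.
#' @export
setClass("SimTruth",
  representation(chrom = "character", pos = "integer",
                 dosageB = "matrix", tract = "numeric",
                 carrierPop = "character", sweepPos = "integer",
                 bsLoci = "data.frame", popFreqs = "matrix",
                 altIsDerived = "logical", seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- character()
  d <- object@dosageB[is.finite(object@dosageB)]
  if (length(d) && (min(d) < -1e-9 || max(d) > 1 + 1e-9))
    msg <- c(msg, "true dosages must lie in [0, 1]")
  if (length(object@tract) && length(object@tract) != 2L)
    msg <- c(msg, "tract must be c(start, end)")
  if (length(object@tract) == 2L && object@tract[2] <= object@tract[1])
    msg <- c(msg, "tract end must exceed tract start")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d site(s) on %s, seed %d\n",
              nrow(object@dosageB), object@chrom, object@seed))
  if (length(object@tract) == 2L)
    cat(sprintf("  tract [%d, %d) in %s, sweep focal at %d\n",
                object@tract[1], object@tract[2], object@carrierPop,
                object@sweepPos))
  if (nrow(object@bsLoci))
    cat(sprintf("  %d balancing-selection site(s)\n", nrow(object@bsLoci)))
})
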