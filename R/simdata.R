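## Synthetic admixed-cohort generator.
##
## The generator emulates the statistical structure the scans assume:
## Balding-Nichols divergent donor panels and an outgroup, hybrid
## populations whose haplotypes are Markov ancestry mosaics of two
## donors, one introgressed-and-swept tract fixed in one hybrid
## population, and clusters of intermediate-frequency balancing-selection
## loci shared by every population.  It is a mosaic-frequency model, not
## a coalescent: fast, analytically transparent, and sufficient for every
## downstream statistic.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: one 1-Mb
#' chromosome carrying 20,000 SNPs; two donor panels (Balding-Nichols
#' F = 0.1, n = 15 each) and an outgroup (F = 0.9, n = 10, 5% fixed
#' differences); two hybrid populations of 10 (donor-B admixture 0.5 and
#' 0.1) whose ancestry switches at a rate giving ~20 segments per
#' chromosome after 100 generations of admixture; a 60-kb introgressed
#' sweep tract fixed in `hybridN` (the donor panel carries the swept
#' core at frequency 0.9); and three 24-SNP balancing-selection clusters
#' at folded frequency 0.5 (two species-wide, one inside the tract),
#' each centred within a single 10-kb bin.
#' Mutation rate 2.5e-9 per bp per generation and a 15-year generation
#' time are carried as annotation for time conversions.
#'
#' @param nSites total SNP count (background plus planted clusters).
#' @param chromLengthBp chromosome length in bp.
#' @param chrom chromosome label.
#' @param donorF named Balding-Nichols divergence per donor population.
#' @param donorN named sample sizes per donor population.
#' @param outgroupN,outgroupF outgroup sample size and divergence.
#' @param outgroupFixedFrac fraction of sites fixed in the outgroup for
#'   the allele opposite the common ingroup allele.
#' @param hybrids named list; each element
#'   `list(donorA=, donorB=, alphaB=, n=)` where `alphaB` is the
#'   stationary donor-B ancestry proportion.
#' @param switchRate ancestry switch rate per bp (default 20 expected
#'   segments per chromosome: `20 / chromLengthBp`).
#' @param admixtureGenerations generations since admixture began
#'   (annotation; default 100).
#' @param tract `list(start=, end=, carrierPop=, carrierFreq=,
#'   donorCoreFreq=)` with 0-based half-open coordinates, or NULL for no
#'   tract.  `donorCoreFreq` is the frequency of the swept core
#'   haplotype within the donor-B panel itself: an adaptively
#'   introgressed haplotype is also at high frequency in its donor
#'   population, which is what makes the recipient's tract resemble the
#'   donor.
#' @param sweep `list(focalPos=, breakScaleBp=)`: each carrier haplotype
#'   copies the shared core haplotype exactly over a segment around the
#'   focal site, out to recombination breakpoints drawn exponentially at
#'   scale `breakScaleBp` on either side (beyond them the haplotype is a
#'   fresh donor-B draw), and every carrier derives the focal allele; or
#'   NULL for no sweep.
#' @param bsLoci list of `list(pos=, freq=, widthBp=, nSnps=, kind=)`
#'   balancing-selection clusters (`kind` is "shared" or "tract").
#' @param mu mutation rate per bp per generation (annotation).
#' @param generationTime generation time in years (annotation).
#' @param missingRate per-genotype missingness probability.
#' @param seed random seed; a fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
simConfig <- function(nSites = 20000L,
                      chromLengthBp = 1000000L,
                      chrom = "chr1",
                      donorF = c(donorA = 0.1, donorB = 0.1),
                      donorN = c(donorA = 15L, donorB = 15L),
                      outgroupN = 10L,
                      outgroupF = 0.9,
                      outgroupFixedFrac = 0.05,
                      hybrids = list(
                        hybridN = list(donorA = "donorA", donorB = "donorB",
                                       alphaB = 0.5, n = 10L),
                        hybridS = list(donorA = "donorA", donorB = "donorB",
                                       alphaB = 0.1, n = 10L)),
                      switchRate = NULL,
                      admixtureGenerations = 100L,
                      tract = list(start = 240000L, end = 300000L,
                                   carrierPop = "hybridN", carrierFreq = 1.0,
                                   donorCoreFreq = 0.9),
                      sweep = list(focalPos = 270000L, breakScaleBp = 150000L),
                      bsLoci = list(
                        list(pos = 95000L, freq = 0.5, widthBp = 1000L,
                             nSnps = 24L, kind = "shared"),
                        list(pos = 705000L, freq = 0.5, widthBp = 1000L,
                             nSnps = 24L, kind = "shared"),
                        list(pos = 255000L, freq = 0.5, widthBp = 1000L,
                             nSnps = 24L, kind = "tract")),
                      mu = 2.5e-9,
                      generationTime = 15,
                      missingRate = 0,
                      seed = 42L) {
  cfg <- list(nSites = as.integer(nSites),
              chromLengthBp = as.integer(chromLengthBp), chrom = chrom,
              donorF = unlist(donorF), donorN = unlist(donorN),
              outgroupN = as.integer(outgroupN),
              outgroupF = outgroupF, outgroupFixedFrac = outgroupFixedFrac,
              hybrids = hybrids,
              switchRate = switchRate %||% (20 / chromLengthBp),
              admixtureGenerations = as.integer(admixtureGenerations),
              tract = tract, sweep = sweep, bsLoci = bsLoci,
              mu = mu, generationTime = generationTime,
              missingRate = missingRate, seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  if (length(cfg$donorF) < 2L)
    .stopf("at least two donor populations required")
  if (any(cfg$donorF <= 0 | cfg$donorF >= 1))
    .stopf("donor F must lie in (0, 1)")
  if (!identical(sort(names(cfg$donorF)), sort(names(cfg$donorN))))
    .stopf("donorF and donorN must name the same populations")
  for (h in names(cfg$hybrids)) {
    hy <- cfg$hybrids[[h]]
    if (!all(c(hy$donorA, hy$donorB) %in% names(cfg$donorF)))
      .stopf("hybrid %s names unknown donor panel(s)", h)
    if (hy$alphaB < 0 || hy$alphaB > 1)
      .stopf("hybrid %s: alphaB must lie in [0, 1]", h)
  }
  if (!is.null(cfg$tract)) {
    tr <- cfg$tract
    if (tr$start < 0 || tr$end > cfg$chromLengthBp || tr$end <= tr$start)
      .stopf("tract [%d, %d) outside chromosome of %d bp",
             tr$start, tr$end, cfg$chromLengthBp)
    if (!tr$carrierPop %in% names(cfg$hybrids))
      .stopf("tract carrier '%s' is not a hybrid population", tr$carrierPop)
    if (tr$carrierFreq < 0 || tr$carrierFreq > 1)
      .stopf("tract carrier frequency must lie in [0, 1]")
  }
  if (!is.null(cfg$sweep) && !is.null(cfg$tract)) {
    if (cfg$sweep$focalPos <= cfg$tract$start ||
        cfg$sweep$focalPos > cfg$tract$end)
      .stopf("sweep focal site must lie inside the tract")
  }
  nBs <- sum(vapply(cfg$bsLoci, function(b) b$nSnps, integer(1) + 0))
  if (cfg$nSites > 0 && nBs >= cfg$nSites)
    .stopf("balancing-selection clusters (%d SNPs) overflow nSites (%d)",
           nBs, cfg$nSites)
  for (b in cfg$bsLoci) {
    if (b$pos - b$widthBp / 2 < 1 || b$pos + b$widthBp / 2 > cfg$chromLengthBp)
      .stopf("balancing-selection cluster at %d overflows the chromosome", b$pos)
  }
  invisible(TRUE)
}

#' Simulate an admixed cohort with planted selection signals
#'
#' Generates phased haplotypes under the mosaic-frequency model: an
#' ancestral alternate-allele frequency `p ~ U(0.05, 0.95)` per site
#' (the reference allele is ancestral, the alternate derived);
#' per-population frequencies from the Balding-Nichols Beta with the
#' population's F; hybrid haplotypes as Markov donor-ancestry mosaics
#' switching at `switchRate` per bp with stationary donor-B probability
#' `alphaB`; the introgressed tract forced to donor-B ancestry in carrier
#' haplotypes, which copy a shared core haplotype with a probability that
#' decays with distance from the focal site (all carriers derive the
#' focal allele); and balancing-selection clusters where every
#' population's folded frequency is set to ~0.5 with small jitter.
#'
#' @param cfg a [simConfig()] list.
#' @return list with elements `genotypes` ([GenotypeData-class], phased),
#'   `popmap` ([PopMap-class] with four-taxon and donor roles), and
#'   `truth` ([SimTruth-class]).
#' @export
simulateCohort <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "sim_config"))
  .validate_sim_config(cfg)
  set.seed(cfg$seed)
  if (cfg$nSites == 0L) return(.empty_cohort(cfg))
  L <- cfg$chromLengthBp
  nBs <- sum(vapply(cfg$bsLoci, function(b) as.integer(b$nSnps), integer(1)))
  nBg <- cfg$nSites - nBs
  bsPos <- unlist(lapply(cfg$bsLoci, function(b) {
    lo <- as.integer(b$pos - b$widthBp / 2)
    as.integer(round(seq(lo, lo + b$widthBp, length.out = b$nSnps)))
  }))
  bsKind <- unlist(lapply(cfg$bsLoci, function(b) rep(b$kind, b$nSnps)))
  avail <- if (length(bsPos)) setdiff(seq_len(L), bsPos) else seq_len(L)
  pos <- sort(sample(avail, nBg))      # unique, disjoint from clusters
  ord <- order(c(pos, bsPos))
  kind <- c(rep("background", nBg), bsKind)[ord]
  pos <- c(pos, bsPos)[ord]
  S <- length(pos)
  bsIdx <- which(kind != "background")

  ## population layout
  donorPops <- names(cfg$donorF)
  hybPops <- names(cfg$hybrids)
  popSizes <- c(cfg$donorN, outgroup = cfg$outgroupN,
                setNames(vapply(cfg$hybrids, function(h) as.integer(h$n),
                                integer(1)), hybPops))
  popNames <- c(donorPops, "outgroup", hybPops)
  samples <- unlist(lapply(popNames, function(p)
    sprintf("%s_%02d", p, seq_len(popSizes[[p]]))))
  popOfSample <- rep(popNames, times = popSizes[popNames])

  ## frequencies: ancestral, per-donor, outgroup
  pAnc <- runif(S, 0.05, 0.95)
  popFreq <- matrix(NA_real_, S, length(popNames),
                    dimnames = list(NULL, popNames))
  for (d in donorPops) {
    Fd <- cfg$donorF[[d]]
    c0 <- (1 - Fd) / Fd
    popFreq[, d] <- rbeta(S, pAnc * c0, (1 - pAnc) * c0)
  }
  cO <- (1 - cfg$outgroupF) / cfg$outgroupF
  pO <- rbeta(S, pAnc * cO, (1 - pAnc) * cO)
  fixed <- runif(S) < cfg$outgroupFixedFrac
  pO[fixed] <- ifelse(pAnc[fixed] < 0.5, 1, 0)
  popFreq[, "outgroup"] <- pO

  ## haplotype containers
  nHapPer <- 2L * unlist(popSizes[popNames])
  hapPop <- rep(popNames, times = nHapPer)
  H <- matrix(0L, S, sum(nHapPer))
  trueB <- matrix(NA_real_, S, length(samples),
                  dimnames = list(NULL, samples))

  for (d in donorPops) {
    cols <- which(hapPop == d)
    H[, cols] <- rbinom(S * length(cols), 1L, popFreq[, d])
    trueB[, popOfSample == d] <- if (d == "donorB") 1 else 0
  }
  cols <- which(hapPop == "outgroup")
  H[, cols] <- rbinom(S * length(cols), 1L, popFreq[, "outgroup"])

  ## hybrid ancestry mosaics (states: TRUE = donorB ancestry)
  lam <- cfg$switchRate
  gaps <- diff(pos)
  pSwitch <- 1 - exp(-lam * gaps)
  hybStates <- list(); hybProbs <- list()
  for (h in hybPops) {
    hy <- cfg$hybrids[[h]]
    cols <- which(hapPop == h)
    nh <- length(cols)
    st <- matrix(FALSE, S, nh)
    st[1, ] <- runif(nh) < hy$alphaB
    for (i in 2:S) {
      switch_ <- runif(nh) < pSwitch[i - 1L]
      st[i, ] <- ifelse(switch_, runif(nh) < hy$alphaB, st[i - 1L, ])
    }
    fA <- popFreq[, hy$donorA]; fB <- popFreq[, hy$donorB]
    pDraw <- ifelse(st, fB, fA)
    H[, cols] <- rbinom(S * nh, 1L, as.vector(pDraw))
    hybStates[[h]] <- st
    hybProbs[[h]] <- pDraw     # per-haplotype generative allele probability
  }

  ## introgressed sweep tract: carrier haplotypes forced to donor-B
  ## ancestry; each copies the shared swept core haplotype exactly over a
  ## segment delimited by recombination breakpoints around the focal site
  tractVec <- numeric(0); carrierPop <- ""; sweepPos <- 0L
  if (!is.null(cfg$tract)) {
    tr <- cfg$tract
    carrierPop <- tr$carrierPop
    hy <- cfg$hybrids[[carrierPop]]
    cols <- which(hapPop == carrierPop)
    inTract <- pos > tr$start & pos <= tr$end   # 0-based half-open
    idxT <- which(inTract)
    carriers <- runif(length(cols)) < tr$carrierFreq
    fB <- popFreq[, hy$donorB]
    core <- rbinom(S, 1L, fB)
    if (!is.null(cfg$sweep)) {
      sw <- cfg$sweep
      focalIdx <- idxT[which.min(abs(pos[idxT] - sw$focalPos))]
      sweepPos <- pos[focalIdx]
      core[focalIdx] <- 1L
      ## focal derived allele: rare outside the donor-B gene pool
      popFreq[focalIdx, ] <- 0.02
      popFreq[focalIdx, hy$donorB] <- 0.5
      popFreq[focalIdx, "outgroup"] <- 0
      for (pp in popNames) {
        cc <- which(hapPop == pp)
        H[focalIdx, cc] <- rbinom(length(cc), 1L, popFreq[focalIdx, pp])
      }
      bs_ <- sw$breakScaleBp
      wCopy <- exp(-abs(pos - sweepPos) / bs_)   # P(site inside unbroken core)
    } else {
      focalIdx <- idxT[ceiling(length(idxT) / 2)]
      sweepPos <- 0L
      bs_ <- Inf
      wCopy <- rep(1, S)
    }
    anchor <- pos[focalIdx]
    copySegment <- function(hcol) {
      ## exact core copy between exponential breakpoints, fresh donor-B
      ## draw elsewhere in the tract
      left <- anchor - if (is.finite(bs_)) rexp(1, 1 / bs_) else Inf * -1
      right <- anchor + if (is.finite(bs_)) rexp(1, 1 / bs_) else Inf
      if (!is.finite(bs_)) { left <- -Inf; right <- Inf }
      inCore <- pos[idxT] >= left & pos[idxT] <= right
      fresh <- rbinom(length(idxT), 1L, fB[idxT])
      H[idxT, hcol] <<- ifelse(inCore, core[idxT], fresh)
      inCore
    }
    for (k in seq_along(cols)) {
      if (!carriers[k]) next
      hybStates[[carrierPop]][idxT, k] <- TRUE
      copySegment(cols[k])
      hybProbs[[carrierPop]][idxT, k] <-
        wCopy[idxT] * core[idxT] + (1 - wCopy[idxT]) * fB[idxT]
      if (sweepPos > 0L) {
        H[focalIdx, cols[k]] <- 1L
        hybProbs[[carrierPop]][focalIdx, k] <- 1
      }
    }
    ## donor-side sweep: the swept core is also at high frequency in the
    ## donor-B panel (an adaptively introgressed allele rises in its
    ## donor gene pool too)
    qDonor <- tr$donorCoreFreq %||% 0.9
    dcols <- which(hapPop == hy$donorB)
    donorCarrier <- runif(length(dcols)) < qDonor
    for (k in seq_along(dcols)) {
      if (!donorCarrier[k]) next
      copySegment(dcols[k])
      if (sweepPos > 0L) H[focalIdx, dcols[k]] <- 1L
    }
    popFreq[idxT, hy$donorB] <-
      qDonor * (wCopy[idxT] * core[idxT] + (1 - wCopy[idxT]) * fB[idxT]) +
      (1 - qDonor) * fB[idxT]
    if (sweepPos > 0L)
      popFreq[focalIdx, hy$donorB] <- qDonor + (1 - qDonor) * 0.5
    tractVec <- c(tr$start, tr$end)
  }

  ## balancing-selection clusters: every population's folded frequency
  ## pinned near the target with small jitter (standing trans-population
  ## variation, decoupled from local ancestry)
  if (length(bsIdx)) {
    ## per-site target frequencies, in sorted site order
    tgtAll <- c(rep(NA_real_, nBg),
                unlist(lapply(cfg$bsLoci, function(b) rep(b$freq, b$nSnps))))[ord]
    for (i in bsIdx) {
      for (pp in popNames) {
        f <- min(0.6, max(0.4, tgtAll[i] + rnorm(1, 0, 0.01)))
        cc <- which(hapPop == pp)
        cnt <- max(1L, min(length(cc) - 1L, as.integer(round(f * length(cc)))))
        H[i, cc] <- 0L
        H[i, sample(cc, cnt)] <- 1L
        popFreq[i, pp] <- cnt / length(cc)
        if (pp %in% hybPops) hybProbs[[pp]][i, ] <- cnt / length(cc)
      }
    }
  }
  ## hybrid true frequencies: mean generative allele probability
  for (h in hybPops) popFreq[, h] <- rowMeans(hybProbs[[h]])

  ## true dosages for hybrids
  for (h in hybPops) {
    st <- hybStates[[h]]
    sampIdx <- which(popOfSample == h)
    trueB[, sampIdx] <- (st[, seq(1, ncol(st), 2), drop = FALSE] +
                         st[, seq(2, ncol(st), 2), drop = FALSE]) / 2
  }

  ## assemble genotypes, alleles, missingness
  a1 <- H[, seq(1L, ncol(H), by = 2L), drop = FALSE]
  a2 <- H[, seq(2L, ncol(H), by = 2L), drop = FALSE]
  G <- a1 + a2
  colnames(G) <- samples
  hap <- matrix(NA_integer_, S, ncol(H))
  hap[, seq(1L, ncol(hap), 2L)] <- a1
  hap[, seq(2L, ncol(hap), 2L)] <- a2
  colnames(hap) <- paste0(rep(samples, each = 2L), c("_1", "_2"))
  if (cfg$missingRate > 0) {
    drop <- matrix(runif(length(G)) < cfg$missingRate, nrow(G))
    G[drop] <- NA_integer_
    hap[, seq(1L, ncol(hap), 2L)][drop] <- NA_integer_
    hap[, seq(2L, ncol(hap), 2L)][drop] <- NA_integer_
  }
  alleles <- .sim_alleles(S)
  gd <- GenotypeData(G, rep(cfg$chrom, S), pos, alleles$ref, alleles$alt,
                     haplotypes = hap)

  roles <- list(outgroup = c("O", "none"))
  roles[["outgroup"]] <- "O"
  for (d in donorPops) roles[[d]] <- character(0)
  if ("donorA" %in% donorPops) roles[["donorA"]] <- "donorA"
  if ("donorB" %in% donorPops) roles[["donorB"]] <- c("donorB", "P3")
  donors <- list()
  for (h in hybPops) {
    hy <- cfg$hybrids[[h]]
    roles[[h]] <- "hybrid"
    donors[[h]] <- c(donorA = hy$donorA, donorB = hy$donorB)
  }
  if (!is.null(cfg$tract)) {
    cp <- cfg$tract$carrierPop
    roles[[cp]] <- c(roles[[cp]], "P2")
    others <- setdiff(hybPops, cp)
    if (length(others)) roles[[others[1]]] <- c(roles[[others[1]]], "P1")
  } else if (length(hybPops) >= 2) {
    roles[[hybPops[1]]] <- c(roles[[hybPops[1]]], "P2")
    roles[[hybPops[2]]] <- c(roles[[hybPops[2]]], "P1")
  }
  roles <- roles[vapply(roles, length, 1L) > 0]
  popmap <- PopMap(samples, popOfSample, roles = roles, donors = donors)

  truth <- new("SimTruth", chrom = cfg$chrom, pos = as.integer(pos),
               dosageB = trueB,
               tract = tractVec, carrierPop = carrierPop,
               sweepPos = as.integer(sweepPos),
               bsLoci = if (length(bsIdx))
                 data.frame(pos = pos[bsIdx], kind = kind[bsIdx])
               else data.frame(pos = integer(), kind = character()),
               popFreqs = popFreq, altIsDerived = rep(TRUE, S),
               seed = cfg$seed)
  list(genotypes = gd, popmap = popmap, truth = truth)
}

.empty_cohort <- function(cfg) {
  donorPops <- names(cfg$donorF)
  hybPops <- names(cfg$hybrids)
  popSizes <- c(cfg$donorN, outgroup = cfg$outgroupN,
                setNames(vapply(cfg$hybrids, function(h) as.integer(h$n),
                                integer(1)), hybPops))
  popNames <- c(donorPops, "outgroup", hybPops)
  samples <- unlist(lapply(popNames, function(p)
    sprintf("%s_%02d", p, seq_len(popSizes[[p]]))))
  popOfSample <- rep(popNames, times = popSizes[popNames])
  gm <- matrix(integer(), 0, length(samples),
               dimnames = list(NULL, samples))
  gd <- GenotypeData(gm, character(), integer(), character(), character())
  roles <- list(outgroup = "O")
  donors <- list()
  for (h in hybPops) {
    roles[[h]] <- "hybrid"
    donors[[h]] <- c(donorA = cfg$hybrids[[h]]$donorA,
                     donorB = cfg$hybrids[[h]]$donorB)
  }
  truth <- new("SimTruth", chrom = cfg$chrom, pos = integer(),
               dosageB = matrix(numeric(), 0, length(samples),
                                dimnames = list(NULL, samples)),
               tract = numeric(0), carrierPop = "", sweepPos = 0L,
               bsLoci = data.frame(pos = integer(), kind = character()),
               popFreqs = matrix(numeric(), 0, length(popNames),
                                 dimnames = list(NULL, popNames)),
               altIsDerived = logical(), seed = cfg$seed)
  list(genotypes = gd, popmap = PopMap(samples, popOfSample, roles = roles,
                                       donors = donors),
       truth = truth)
}

## deterministic ref/alt pairs cycling through the transitions
.sim_alleles <- function(S) {
  refs <- c("A", "C", "G", "T")[(seq_len(S) - 1L) %% 4L + 1L]
  alts <- c("G", "T", "A", "C")[(seq_len(S) - 1L) %% 4L + 1L]
  list(ref = refs, alt = alts)
}

#' Self-consistency checks of a simulated cohort
#'
#' Verifies that (i) true dosages lie in [0, 1] (donor dosages sum to one
#' by the complementary representation; a violation injected into the
#' truth matrix is reported), (ii) per-population empirical allele
#' frequencies recover the truth (correlation > 0.95 for populations
#' with at least 20 samples), and (iii) the folded SFS of each
#' population conserves the segregating-site count.
#'
#' @param gm a [GenotypeData-class] from [simulateCohort()].
#' @param truth the matching [SimTruth-class].
#' @param popmap the matching [PopMap-class].
#' @return list with `ok` (logical) and `failures` (character vector;
#'   `"no sites"` for an empty cohort).
#' @export
validateSim <- function(gm, truth, popmap) {
  fails <- character()
  if (nSites(gm) == 0L)
    return(list(ok = FALSE, failures = "no sites"))
  d <- truth@dosageB
  bad <- is.finite(d) & (d < -1e-9 | d > 1 + 1e-9)
  if (any(bad))
    fails <- c(fails, sprintf("dosage out of [0,1] at %d entries (donor dosages do not sum to 1)",
                              sum(bad)))
  fr <- alleleFreqs(gm, popmap)
  idx <- match(positions(gm), truth@pos)
  if (anyNA(idx))
    return(list(ok = FALSE, failures = "sites not present in truth record"))
  for (p in colnames(truth@popFreqs)) {
    if (!p %in% colnames(fr$freq)) next
    if (length(samplesOf(popmap, p)) < 20L) next
    cc <- suppressWarnings(cor(fr$freq[, p], truth@popFreqs[idx, p],
                               use = "complete.obs"))
    if (!is.finite(cc) || cc <= 0.95)
      fails <- c(fails, sprintf("frequency recovery failed for %s (r=%.3f)",
                                p, cc))
  }
  for (p in populations(popmap)) {
    if (length(samplesOf(popmap, p)) < 2) next
    sfs <- foldedSfs(gm, popmap, p)
    if (sum(sfs$sfs) != sfs$nSegregating)
      fails <- c(fails, sprintf("SFS conservation failed for %s", p))
  }
  list(ok = length(fails) == 0L, failures = fails)
}

#' Write / read the simulation truth as JSON
#'
#' The JSON records the planted structure (tract, sweep focal site,
#' balancing-selection loci, seed, per-population truth summaries); the
#' full per-sample dosage matrix stays in the in-memory object.
#'
#' @param truth a [SimTruth-class].
#' @param path JSON file.
#' @return `path` invisibly.
#' @export
writeTruthJson <- function(truth, path) {
  obj <- list(chrom = truth@chrom, seed = truth@seed,
              tract = if (length(truth@tract)) truth@tract else NULL,
              carrier_pop = if (nzchar(truth@carrierPop)) truth@carrierPop else NULL,
              sweep_pos = if (truth@sweepPos > 0) truth@sweepPos else NULL,
              bs_loci = truth@bsLoci,
              n_sites = nrow(truth@dosageB),
              populations = colnames(truth@popFreqs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
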