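## Folded-beta balancing-selection scan: per-site beta scores with
## per-population FDR, cross-population shared-site intersection, 10-kb
## bin summaries with a diversity contrast, and beta-by-ADD
## classification of significant sites.

#' Folded beta scores for one population
#'
#' For each core SNP (folded frequency >= `minFreq`), flanking SNPs
#' within `halfwidthBp` are weighted by a triangular frequency-similarity
#' kernel `w_i = max(0, 1 - |f_i - f_core| / maxDiff)` on folded
#' frequencies, and beta is the similarity-weighted SNP count minus its
#' neutral expectation (flank SNP density times the mean kernel weight
#' under the Watterson-shaped neutral folded SFS).  Clusters of SNPs at
#' matching intermediate frequency therefore score high; a core with no
#' flanking SNPs scores negative.  P-values come from a robust normal
#' approximation to the genome-wide beta distribution (median/MAD
#' Z-scores, upper tail), with Benjamini-Hochberg q-values per
#' population.
#'
#' @param gd a [GenotypeData-class].
#' @param popmap a [PopMap-class].
#' @param population population to scan (needs >= 4 haplotypes).
#' @param minFreq minimum folded frequency of a core SNP (default 0.1).
#' @param halfwidthBp flank half-width in bp (default 1000).
#' @param maxDiff kernel width on the folded-frequency scale
#'   (default 0.1).
#' @return data.frame with `chrom`, `pos`, `f_core`, `beta`, `p`, `q`
#'   for the population's core sites.
#' @export
betaScores <- function(gd, popmap, population, minFreq = 0.1,
                       halfwidthBp = 1000L, maxDiff = 0.1) {
  ss <- samplesOf(popmap, population)
  if (2L * length(ss) < 4L)
    .stopf("population '%s' has fewer than 4 haplotypes", population)
  g <- genotypes(gd)[, ss, drop = FALSE]
  nm <- rowSums(!is.na(g))
  nHap <- 2 * nm
  p <- ifelse(nm > 0, rowSums(g, na.rm = TRUE) / nHap, NA_real_)
  folded <- pmin(p, 1 - p)
  seg <- is.finite(folded) & folded > 0
  pos <- positions(gd); chv <- chroms(gd)
  n <- 2L * length(ss)
  ## neutral folded SFS weights psi_k ~ (1/k + 1/(n-k)), k = 1..n/2
  ks <- seq_len(n %/% 2L)
  psi <- (1 / ks + 1 / (n - ks)) / ifelse(ks == n - ks, 2, 1)
  fk <- ks / n
  meanKernel <- function(fc)
    sum(pmax(0, 1 - abs(fk - fc) / maxDiff) * psi) / sum(psi)
  cores <- which(seg & folded >= minFreq)
  if (!length(cores))
    return(data.frame(chrom = character(), pos = integer(),
                      f_core = numeric(), beta = numeric(), p = numeric(),
                      q = numeric()))
  out <- data.frame(chrom = chv[cores], pos = pos[cores],
                    f_core = folded[cores], beta = NA_real_)
  for (cc in unique(chv)) {
    onChr <- which(seg & chv == cc)
    if (!length(onChr)) next
    cpos <- pos[onChr]
    cf <- folded[onChr]
    density <- length(onChr) / max(1, max(cpos) - min(cpos) + 1)
    sel <- which(chv[cores] == cc)
    ci <- cores[sel]
    lo <- findInterval(pos[ci] - halfwidthBp - 0.5, cpos) + 1L
    hi <- findInterval(pos[ci] + halfwidthBp + 0.5, cpos)
    beta <- numeric(length(ci))
    for (k in seq_along(ci)) {
      rng <- if (hi[k] >= lo[k]) lo[k]:hi[k] else integer(0)
      rng <- rng[onChr[rng] != ci[k]]
      sw <- if (length(rng))
        sum(pmax(0, 1 - abs(cf[rng] - folded[ci[k]]) / maxDiff)) else 0
      expS <- density * 2 * halfwidthBp * meanKernel(folded[ci[k]])
      beta[k] <- sw - expS
    }
    out$beta[sel] <- beta
  }
  medb <- median(out$beta)
  madb <- mad(out$beta)
  if (madb == 0) madb <- max(sd(out$beta), .Machine$double.eps)
  z <- (out$beta - medb) / madb
  out$p <- pnorm(z, lower.tail = FALSE)
  out$q <- .bh(out$p)
  out
}

#' Intersection of significant balancing-selection sites
#'
#' Sites with q below `fdr` in every population's score table, over the
#' common site universe (the intersection of the tables' core-site
#' positions).
#'
#' @param tables named list of [betaScores()] data.frames (>= 2).
#' @param fdr per-population FDR threshold (default 0.01).
#' @return list with `shared` (positions significant in all
#'   populations), `perPop` (named significant-site counts on the common
#'   universe) and `nUniverse`.
#' @export
sharedBsSites <- function(tables, fdr = 0.01) {
  if (length(tables) < 2L) .stopf("need score tables for >= 2 populations")
  universes <- lapply(tables, function(t) t$pos)
  universe <- Reduce(intersect, universes)
  if (!length(universe))
    .stopf("sharedBsSites: population score tables have disjoint site universes")
  sigSets <- lapply(tables, function(t)
    intersect(t$pos[t$q < fdr & is.finite(t$q)], universe))
  list(shared = sort(Reduce(intersect, sigSets)),
       perPop = vapply(sigSets, length, integer(1)),
       nUniverse = length(universe))
}

#' Balancing-selection bins with a diversity contrast
#'
#' Tiles each chromosome with `binBp` bins (0-based half-open), counts
#' the shared balancing-selection sites per bin, flags bins with at
#' least `minSites` sites, and contrasts mean nucleotide diversity of
#' qualifying bins against the genome-wide mean (mean of the `pi_*`
#' columns of the supplied window table, matched on bin coordinates).
#'
#' @param sharedPos 1-based positions of shared significant sites.
#' @param chromLengths named chromosome lengths (bp).
#' @param binBp bin size (default 10000).
#' @param minSites qualifying threshold (default 15).
#' @param diversity optional [windowedDiversity()] data.frame computed
#'   at the same window size, for the pi contrast.
#' @param chrom chromosome label of `sharedPos` sites (single label or
#'   vector; default: the single chromosome in `chromLengths`).
#' @return list with `bins` (data.frame `chrom`, `start`, `end`,
#'   `n_bs_sites`, `qualifies`, and `pi` when supplied), `piQualifying`
#'   and `piGenome` (NA without a diversity table).
#' @export
bsBins <- function(sharedPos, chromLengths, binBp = 10000L, minSites = 15L,
                   diversity = NULL, chrom = NULL) {
  if (is.null(chrom)) {
    if (length(chromLengths) != 1L)
      .stopf("chrom must be given for multi-chromosome input")
    chrom <- rep(names(chromLengths), length(sharedPos))
  } else if (length(chrom) == 1L) chrom <- rep(chrom, length(sharedPos))
  rows <- list()
  for (cc in names(chromLengths)) {
    nBin <- max(1L, as.integer(ceiling(chromLengths[[cc]] / binBp)))
    starts <- (seq_len(nBin) - 1L) * binBp
    cnt <- tabulate(.window_index(sharedPos[chrom == cc], binBp) + 1L, nBin)
    rows[[cc]] <- data.frame(chrom = cc, start = starts,
                             end = pmin(starts + binBp, chromLengths[[cc]]),
                             n_bs_sites = as.integer(cnt),
                             qualifies = cnt >= minSites)
  }
  bins <- do.call(rbind, rows)
  rownames(bins) <- NULL
  piQ <- piG <- NA_real_
  if (!is.null(diversity)) {
    piCols <- grep("^pi_", names(diversity), value = TRUE)
    if (length(piCols)) {
      dpi <- rowMeans(diversity[, piCols, drop = FALSE])
      key <- paste(diversity$chrom, diversity$start)
      bins$pi <- dpi[match(paste(bins$chrom, bins$start), key)]
      piG <- mean(bins$pi, na.rm = TRUE)
      if (any(bins$qualifies))
        piQ <- mean(bins$pi[bins$qualifies], na.rm = TRUE)
    }
  }
  list(bins = bins, piQualifying = piQ, piGenome = piG)
}

#' Classify significant beta sites by ancestry dosage
#'
#' Splits balancing-selection candidates by the hybrid population's ADD:
#' sites with q below `fdr` and ADD at or above `addMin` are
#' donor-derived (signed by the larger population-mean donor dosage at
#' the site); significant sites with ADD below the genome-wide
#' ADD quantile threshold are shared standing variation; significant
#' sites between the two cutoffs are intermediate.  Non-significant
#' sites are `nonsignificant`; significant sites with no ADD value are
#' `unscored`.
#'
#' @param betaTab a [betaScores()] data.frame.
#' @param track a [DosageTrack-class] for the hybrid population.
#' @param fdr beta significance threshold (default 0.01).
#' @param addMin donor-derived ADD cutoff (default 0.5).
#' @param addQuantile quantile defining the low-ADD regime
#'   (default 0.75).
#' @return `betaTab` with added `add` and `class` columns; classes are
#'   `shared-standing`, `donor-derived-A`, `donor-derived-B`,
#'   `intermediate`, `nonsignificant`, `unscored`.
#' @export
betaAddClassify <- function(betaTab, track, fdr = 0.01, addMin = 0.5,
                            addQuantile = 0.75) {
  m <- match(betaTab$pos, positions(track))
  add <- addScores(track)[m]
  thr <- addQuantileMask(track, addQuantile)$threshold
  meanB <- track@meanB[m]
  sig <- is.finite(betaTab$q) & betaTab$q < fdr
  cls <- rep("nonsignificant", nrow(betaTab))
  cls[sig & is.na(add)] <- "unscored"
  donorB <- sig & !is.na(add) & add >= addMin & meanB > 0.5
  donorA <- sig & !is.na(add) & add >= addMin & meanB <= 0.5
  cls[donorA] <- "donor-derived-A"
  cls[donorB] <- "donor-derived-B"
  shared <- sig & !is.na(add) & add < addMin & add < thr
  cls[shared] <- "shared-standing"
  inter <- sig & !is.na(add) & add < addMin & add >= thr
  cls[inter] <- "intermediate"
  betaTab$add <- add
  betaTab$class <- cls
  betaTab
}
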