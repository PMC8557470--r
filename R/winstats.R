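## Per-site allele frequencies, windowed diversity/divergence statistics
## and the folded site-frequency spectrum.

#' Per-site, per-population allele frequencies with outgroup polarization
#'
#' Frequencies are computed over non-missing alleles.  When an outgroup
#' population is given (or carries role "O" in the map), each site is
#' polarized: the ancestral allele is the outgroup majority allele and
#' the derived frequency is the alternate frequency, flipped wherever the
#' outgroup majority is the alternate.  Sites where the outgroup is
#' polymorphic (minor frequency > `maxOutgroupMinor`) or entirely missing
#' are flagged unpolarized and carry NA derived frequencies.
#'
#' @param gd a [GenotypeData-class] object.
#' @param popmap a [PopMap-class]; every sample of `gd` must be mapped.
#' @param outgroup outgroup population label; default: the population
#'   with role "O", if any.
#' @param maxOutgroupMinor maximum outgroup minor-allele frequency for a
#'   site to be considered polarized (default 0.1).
#' @return list with `freq` (sites x populations alternate-allele
#'   frequencies), `nChrom` (non-missing haploid counts), `derived`
#'   (derived-allele frequencies, NA where unpolarized), `polarized`
#'   (logical per site) and `altIsDerived` (logical per site, NA where
#'   unpolarized).
#' @export
alleleFreqs <- function(gd, popmap, outgroup = NULL, maxOutgroupMinor = 0.1) {
  g <- genotypes(gd)
  pops <- popOf(popmap, colnames(g))
  upops <- unique(pops)
  S <- nrow(g)
  freq <- nchrom <- matrix(NA_real_, S, length(upops),
                           dimnames = list(NULL, upops))
  for (p in upops) {
    sub <- g[, pops == p, drop = FALSE]
    nm <- rowSums(!is.na(sub))
    nchrom[, p] <- 2 * nm
    freq[, p] <- ifelse(nm > 0, rowSums(sub, na.rm = TRUE) / (2 * nm), NA_real_)
  }
  outgroup <- outgroup %||% {
    o <- popsWithRole(popmap, "O")
    if (length(o)) o[1] else NULL
  }
  derived <- matrix(NA_real_, S, length(upops), dimnames = list(NULL, upops))
  polarized <- rep(FALSE, S)
  altIsDerived <- rep(NA, S)
  if (!is.null(outgroup)) {
    if (!outgroup %in% upops)
      .stopf("outgroup population '%s' absent from the data", outgroup)
    fo <- freq[, outgroup]
    minor <- pmin(fo, 1 - fo)
    polarized <- !is.na(fo) & minor <= maxOutgroupMinor
    altIsDerived[polarized] <- fo[polarized] < 0.5
    flip <- polarized & !altIsDerived
    derived[polarized, ] <- freq[polarized, , drop = FALSE]
    derived[flip, ] <- 1 - freq[flip, , drop = FALSE]
  }
  list(freq = freq, nChrom = nchrom, derived = derived,
       polarized = polarized, altIsDerived = altIsDerived)
}

## per-site within-population diversity: mean pairwise difference among
## the 2N sampled alleles (unbiased, n(n-1) pairs)
.site_pi <- function(ac, nc) ifelse(nc > 1, 2 * ac * (nc - ac) / (nc * (nc - 1)), 0)

#' Windowed diversity and divergence
#'
#' Tiles each chromosome with non-overlapping windows of `windowBp`
#' (0-based half-open; the last window is truncated at the chromosome
#' end so the partition covers the chromosome exactly) and computes, per
#' window: per-population nucleotide diversity pi (mean pairwise
#' difference per bp; monomorphic positions count as invariant, so the
#' denominator is the window length), pairwise absolute divergence D_XY
#' (mean between-population pairwise difference per bp; for a population
#' against itself this reduces to its pi), and pairwise Hudson F_ST as a
#' ratio of sums over the window's sites.  Windows with no SNPs carry
#' zeros and `n_snps = 0`.  Hudson F_ST is not clamped: values are <= 1
#' and may be slightly negative near panmixia.
#'
#' @param gd a [GenotypeData-class] object.
#' @param popmap a [PopMap-class].
#' @param windowBp window size in bp (default 10000).
#' @param populations populations to include (default: all mapped).
#' @param chromLengths named chromosome lengths in bp; default: the
#'   largest observed position per chromosome, rounded up to a full
#'   window.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`,
#'   `pi_<pop>`, `dxy_<p1>_<p2>` and `fst_<p1>_<p2>` columns.
#' @export
windowedDiversity <- function(gd, popmap, windowBp = 10000L,
                              populations = NULL, chromLengths = NULL) {
  g <- genotypes(gd)
  pops <- popOf(popmap, colnames(g))
  upops <- populations %||% unique(pops)
  pos <- positions(gd)
  chv <- chroms(gd)
  chrs <- unique(chv)
  if (is.null(chromLengths)) {
    chromLengths <- vapply(chrs, function(cc)
      as.numeric(ceiling(max(pos[chv == cc]) / windowBp) * windowBp), 0)
  }
  ac <- nc <- matrix(0, nrow(g), length(upops), dimnames = list(NULL, upops))
  for (p in upops) {
    sub <- g[, pops == p, drop = FALSE]
    nc[, p] <- 2 * rowSums(!is.na(sub))
    ac[, p] <- rowSums(sub, na.rm = TRUE)
  }
  pairs <- if (length(upops) > 1) utils::combn(upops, 2, simplify = FALSE)
           else list()
  rows <- list()
  for (cc in names(chromLengths)) {
    Lc <- chromLengths[[cc]]
    nWin <- max(1L, as.integer(ceiling(Lc / windowBp)))
    starts <- (seq_len(nWin) - 1L) * windowBp
    ends <- pmin(starts + windowBp, Lc)
    onChr <- which(chv == cc)
    widx <- .window_index(pos[onChr], windowBp) + 1L
    df <- data.frame(chrom = cc, start = starts, end = ends,
                     n_snps = as.integer(tabulate(widx, nWin)))
    lens <- ends - starts
    winSum <- function(v) {
      v[!is.finite(v)] <- 0
      out <- numeric(nWin)
      t <- rowsum(v, widx)
      out[as.integer(rownames(t))] <- t
      out
    }
    for (p in upops) {
      sp <- .site_pi(ac[onChr, p], nc[onChr, p])
      df[[paste0("pi_", p)]] <- winSum(sp) / lens
    }
    for (pr in pairs) {
      p1 <- pr[1]; p2 <- pr[2]
      n1 <- nc[onChr, p1]; n2 <- nc[onChr, p2]
      f1 <- ifelse(n1 > 0, ac[onChr, p1] / n1, NA_real_)
      f2 <- ifelse(n2 > 0, ac[onChr, p2] / n2, NA_real_)
      dxy <- f1 * (1 - f2) + f2 * (1 - f1)
      num <- (f1 - f2)^2 -
        ifelse(n1 > 1, f1 * (1 - f1) / (n1 - 1), 0) -
        ifelse(n2 > 1, f2 * (1 - f2) / (n2 - 1), 0)
      df[[paste0("dxy_", p1, "_", p2)]] <- winSum(dxy) / lens
      sn <- winSum(num); sd_ <- winSum(dxy)
      df[[paste0("fst_", p1, "_", p2)]] <- ifelse(sd_ > 0, sn / sd_, NA_real_)
    }
    rows[[cc]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise D_XY between two sample sets at single sites
#'
#' Mean pairwise difference between haplotype draws from the two sets,
#' excluding self-pairs, so that `dxySites(x, A, A)` equals the
#' within-set diversity pi.  Used by the identity tests; the windowed
#' scan uses [windowedDiversity()].
#'
#' @param gd a [GenotypeData-class].
#' @param samples1,samples2 sample id vectors.
#' @return per-site mean pairwise difference (unit: differences per
#'   site; divide by span for per-bp values).
#' @export
dxySites <- function(gd, samples1, samples2) {
  g <- genotypes(gd)
  s1 <- g[, samples1, drop = FALSE]
  s2 <- g[, samples2, drop = FALSE]
  n1 <- 2 * rowSums(!is.na(s1)); c1 <- rowSums(s1, na.rm = TRUE)
  n2 <- 2 * rowSums(!is.na(s2)); c2 <- rowSums(s2, na.rm = TRUE)
  same <- identical(sort(samples1), sort(samples2))
  diffs <- c1 * (n2 - c2) + c2 * (n1 - c1)
  npairs <- if (same) n1 * (n1 - 1) else n1 * n2
  ifelse(npairs > 0, diffs / npairs, NA_real_)
}

#' Folded site-frequency spectrum of one population
#'
#' Histogram of minor-allele counts over the population's segregating
#' sites.  Sites with any missing genotype in the selected samples are
#' dropped (their count is reported); monomorphic sites are excluded.
#'
#' @param gd a [GenotypeData-class].
#' @param popmap a [PopMap-class].
#' @param population population label (needs >= 2 samples, i.e. 4
#'   haplotypes).
#' @return list with `population`, `nHap`, `sfs` (counts xi_1 ..
#'   xi_floor(n/2)), `nDropped` and `nSegregating`
#'   (`sum(sfs) == nSegregating` always).
#' @export
foldedSfs <- function(gd, popmap, population) {
  ss <- samplesOf(popmap, population)
  if (length(ss) < 2L) .stopf("population '%s' has fewer than 2 samples",
                              population)
  g <- genotypes(gd)[, ss, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0L
  nDropped <- sum(!complete)
  g <- g[complete, , drop = FALSE]
  n <- 2L * length(ss)
  ac <- rowSums(g)
  minor <- pmin(ac, n - ac)
  minor <- minor[minor > 0]
  sfs <- tabulate(minor, nbins = n %/% 2L)
  list(population = population, nHap = n, sfs = sfs,
       nDropped = nDropped, nSegregating = length(minor))
}
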