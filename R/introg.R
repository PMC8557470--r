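## Four-taxon introgression scan: per-site ABBA/BABA pattern weights,
## windowed D / fdM / distance-fraction statistics, and genome-wide
## Z-score + FDR outlier calling.

#' Four-taxon scan configuration
#'
#' @param P1,P2,P3,O the four distinct population labels: P1 and P2 the
#'   sister recipients, P3 the candidate donor, O the outgroup used for
#'   polarization.  Positive statistics indicate P3 -> P2 gene flow,
#'   negative P3 -> P1.
#' @param windowBp non-overlapping window size (default 10000).
#' @param minSnps minimum polarized biallelic SNPs per window; windows
#'   below this are masked (default 100).
#' @return a `four_taxon_config` list.
#' @export
fourTaxonConfig <- function(P1, P2, P3, O, windowBp = 10000L,
                            minSnps = 100L) {
  labs <- c(P1, P2, P3, O)
  if (anyDuplicated(labs)) .stopf("P1, P2, P3 and O must be distinct")
  structure(list(P1 = P1, P2 = P2, P3 = P3, O = O,
                 windowBp = as.integer(windowBp),
                 minSnps = as.integer(minSnps)),
            class = "four_taxon_config")
}

#' Per-site ABBA/BABA pattern weights
#'
#' Frequency-based site patterns from derived-allele frequencies
#' (p1, p2, p3, pO): `ABBA = (1-p1) p2 p3 (1-pO)` and
#' `BABA = p1 (1-p2) p3 (1-pO)`.  Unpolarized sites (NA derived
#' frequency in any taxon) are excluded; their count is returned.
#'
#' @param derived sites x populations matrix of derived-allele
#'   frequencies (as from [alleleFreqs()]).
#' @param cfg a [fourTaxonConfig()].
#' @return list with `patterns` (data.frame `abba`, `baba` for usable
#'   sites), `used` (logical per input site) and `nExcluded`.
#' @export
sitePatterns <- function(derived, cfg) {
  need <- c(cfg$P1, cfg$P2, cfg$P3, cfg$O)
  miss <- setdiff(need, colnames(derived))
  if (length(miss)) .stopf("populations absent from frequency matrix: %s",
                           paste(miss, collapse = ", "))
  p1 <- derived[, cfg$P1]; p2 <- derived[, cfg$P2]
  p3 <- derived[, cfg$P3]; pO <- derived[, cfg$O]
  used <- is.finite(p1) & is.finite(p2) & is.finite(p3) & is.finite(pO)
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  list(patterns = data.frame(abba = abba[used], baba = baba[used]),
       used = used, nExcluded = sum(!used))
}

## per-site fdM denominator: dynamic-donor substitution.  When p2 >= p1
## the denominator site pattern puts the stronger of (P2, P3) in both
## donor slots; when p1 > p2, symmetrically with a sign flip, making the
## windowed statistic antisymmetric under P1 <-> P2.
.fdm_denominator <- function(p1, p2, p3, pO) {
  abba <- function(a, b, c, d) (1 - a) * b * c * (1 - d)
  baba <- function(a, b, c, d) a * (1 - b) * c * (1 - d)
  pD2 <- pmax(p2, p3)
  pD1 <- pmax(p1, p3)
  ifelse(p2 >= p1,
         abba(p1, pD2, pD2, pO) - baba(p1, pD2, pD2, pO),
         -(abba(pD1, p2, pD1, pO) - baba(pD1, p2, pD1, pO)))
}

#' Windowed four-taxon introgression statistics
#'
#' Per non-overlapping window (each chromosome treated independently):
#' Patterson's `D = sum(ABBA-BABA) / sum(ABBA+BABA)`; `fdM` with the
#' same numerator and the dynamic-donor denominator (antisymmetric under
#' P1 <-> P2, range [-1, 1]); and the distance fraction
#' `d_f = (Dxy(P1,P3) - Dxy(P2,P3)) / (Dxy(P1,P3) + Dxy(P2,P3))`, a
#' purely distance-based introgression estimator on the same [-1, 1]
#' scale that is less sensitive to gene-flow timing.  Windows with fewer
#' than `minSnps` usable (polarized, biallelic) SNPs are masked (NA);
#' windows with a zero denominator carry NA for that statistic.
#'
#' @param gd a [GenotypeData-class].
#' @param popmap a [PopMap-class].
#' @param cfg a [fourTaxonConfig()].
#' @param chromLengths optional named chromosome lengths (bp).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `n_snps`, `D`, `f_dM`, `d_f`.
#' @export
windowDstats <- function(gd, popmap, cfg, chromLengths = NULL) {
  fr <- alleleFreqs(gd, popmap, outgroup = cfg$O)
  d <- fr$derived
  p1 <- d[, cfg$P1]; p2 <- d[, cfg$P2]; p3 <- d[, cfg$P3]; pO <- d[, cfg$O]
  used <- is.finite(p1) & is.finite(p2) & is.finite(p3) & is.finite(pO)
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  den <- .fdm_denominator(p1, p2, p3, pO)
  d13 <- p1 * (1 - p3) + p3 * (1 - p1)
  d23 <- p2 * (1 - p3) + p3 * (1 - p2)
  pos <- positions(gd); chv <- chroms(gd)
  chrs <- unique(chv)
  wbp <- cfg$windowBp
  if (is.null(chromLengths))
    chromLengths <- vapply(chrs, function(cc)
      as.numeric(ceiling(max(pos[chv == cc]) / wbp) * wbp), 0)
  rows <- list()
  for (cc in names(chromLengths)) {
    nWin <- max(1L, as.integer(ceiling(chromLengths[[cc]] / wbp)))
    onChr <- chv == cc & used
    widx <- .window_index(pos[onChr], wbp) + 1L
    winSum <- function(v) {
      out <- numeric(nWin)
      t <- rowsum(v[onChr], widx)
      out[as.integer(rownames(t))] <- t
      out
    }
    n_snps <- as.integer(tabulate(widx, nWin))
    sA <- winSum(abba); sB <- winSum(baba)
    sDen <- winSum(den)
    s13 <- winSum(d13); s23 <- winSum(d23)
    D <- ifelse(sA + sB > 0, (sA - sB) / (sA + sB), NA_real_)
    fdm <- ifelse(abs(sDen) > 0, (sA - sB) / sDen, NA_real_)
    df_ <- ifelse(s13 + s23 > 0, (s13 - s23) / (s13 + s23), NA_real_)
    mask <- n_snps < cfg$minSnps
    D[mask] <- fdm[mask] <- df_[mask] <- NA_real_
    starts <- (seq_len(nWin) - 1L) * wbp
    rows[[cc]] <- data.frame(chrom = cc, start = starts,
                             end = pmin(starts + wbp, chromLengths[[cc]]),
                             n_snps = n_snps, D = D, f_dM = fdm, d_f = df_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide Z-score + FDR outlier windows
#'
#' Pools all unmasked windows genome-wide, assigns each window a Z-score
#' from the genome-wide mean and standard deviation of the chosen
#' statistic, converts to a one-sided normal p-value in the chosen
#' direction (positive = P3 -> P2 gene flow), applies Benjamini-Hochberg
#' correction, and flags windows with q below `fdr`.
#'
#' @param records data.frame from [windowDstats()].
#' @param statistic column to test (default `"d_f"`).
#' @param fdr FDR threshold (default 0.05).
#' @param direction `"positive"`, `"negative"` or `"both"`.
#' @return `records` with added `z`, `p`, `q` and `outlier` columns
#'   (NA/FALSE for masked windows).
#' @export
outlierWindows <- function(records, statistic = "d_f", fdr = 0.05,
                           direction = c("positive", "negative", "both")) {
  direction <- match.arg(direction)
  x <- records[[statistic]]
  if (is.null(x)) .stopf("no column '%s' in records", statistic)
  ok <- is.finite(x)
  if (sum(ok) < 30L)
    .stopf("outlierWindows: only %d unmasked windows (need >= 30 for a genome-wide null)",
           sum(ok))
  mu <- mean(x[ok]); sdv <- sd(x[ok])
  z <- p <- q <- rep(NA_real_, nrow(records))
  outlier <- rep(FALSE, nrow(records))
  if (sdv == 0) {
    .warnf("outlierWindows: zero genome-wide SD; no outliers")
    z[ok] <- 0; p[ok] <- 1; q[ok] <- 1
  } else {
    z[ok] <- (x[ok] - mu) / sdv
    p[ok] <- switch(direction,
                    positive = pnorm(z[ok], lower.tail = FALSE),
                    negative = pnorm(z[ok]),
                    both = 2 * pnorm(abs(z[ok]), lower.tail = FALSE))
    q[ok] <- .bh(p[ok])
    outlier[ok] <- q[ok] < fdr
  }
  records$z <- z; records$p <- p; records$q <- q; records$outlier <- outlier
  records
}

#' @importFrom stats sd
NULL
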